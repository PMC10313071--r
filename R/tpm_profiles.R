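# Gene-centric metagenomic profiling over annotated ORF tables: TPM
# normalization, KO -> gene labeling, nosZ clade I/II discrimination,
# per-taxon aggregation and gene-by-taxon modularity matrices.

#' KO number to denitrification gene label mapping
#'
#' The canonical map: napA K02567, nirS K15864, nirK K00368, nosZ K00376,
#' plus norB K04561 (NO reductase subunit B). nosZ is later split into
#' clades I and II from reference hits. Extend or override via the `ko_map`
#' argument of [label_genes()].
#' @export
DENIT_KO_MAP <- c(K02567 = "napA", K15864 = "nirS", K00368 = "nirK",
                  K04561 = "norB", K00376 = "nosZ")

#' Gene labels in pathway order (nosZ split into clades)
#' @export
DENIT_GENES <- c("napA", "nirS", "nirK", "norB", "nosZ_I", "nosZ_II")

#' Label ORFs with denitrification gene names from KO ids
#'
#' @param orfs data.frame with a `ko_id` column.
#' @param ko_map named character vector KO -> gene label; extend or override
#'   to add genes (e.g. a norB KO from a custom annotation).
#' @return `orfs` with a `gene_label` column (NA for non-denitrification KOs).
#' @export
label_genes <- function(orfs, ko_map = DENIT_KO_MAP) {
  stopifnot(is.data.frame(orfs), "ko_id" %in% names(orfs))
  orfs$gene_label <- unname(ko_map[orfs$ko_id])
  orfs
}

#' Transcripts-per-million normalization
#'
#' TPM_i = (count_i / length_i) / sum_j (count_j / length_j) x 10^6, computed
#' per sample over ALL ORFs in the table (not per gene subset), matching
#' annotation-stage normalization. Sums to 10^6 per sample whenever any read
#' maps; an all-zero sample yields all-zero TPM with a warning.
#'
#' @param orfs data.frame with `sample_id`, `length_bp`, `read_count`.
#' @return `orfs` with a `tpm` column.
#' @export
compute_tpm <- function(orfs) {
  stopifnot(is.data.frame(orfs),
            all(c("sample_id", "length_bp", "read_count") %in% names(orfs)))
  if (any(orfs$length_bp <= 0)) stop("ORF lengths must be > 0", call. = FALSE)
  if (any(orfs$read_count < 0)) stop("read counts must be >= 0", call. = FALSE)
  rate <- orfs$read_count / orfs$length_bp
  denom <- stats::ave(rate, orfs$sample_id, FUN = sum)
  orfs$tpm <- ifelse(denom > 0, rate / denom * 1e6, 0)
  if (any(denom == 0)) {
    warning("sample(s) with zero mapped reads; TPM set to 0", call. = FALSE)
  }
  orfs
}

#' Discriminate nosZ clades from top reference hits
#'
#' Each nosZ ORF carries up to 10 ordered reference hits labeled clade I or
#' II; assignment is by strict majority over the available hits. Ties and
#' empty hit lists yield `"unassigned"`, which is reported rather than
#' dropped. Deterministic and invariant to hit order.
#'
#' @param hits data.frame with `orf_id`, `clade` ("I"/"II"), optionally
#'   `hit_rank`.
#' @return data.frame `orf_id`, `assigned_clade` ("nosZ_I", "nosZ_II" or
#'   "unassigned").
#' @export
split_nosz <- function(hits) {
  stopifnot(is.data.frame(hits), all(c("orf_id", "clade") %in% names(hits)))
  if (!all(hits$clade %in% c("I", "II"))) {
    stop("clade must be 'I' or 'II'", call. = FALSE)
  }
  counts <- table(hits$orf_id, hits$clade)
  n_i <- if ("I" %in% colnames(counts)) counts[, "I"] else rep(0, nrow(counts))
  n_ii <- if ("II" %in% colnames(counts)) counts[, "II"] else rep(0, nrow(counts))
  assigned <- ifelse(n_i > n_ii, "nosZ_I",
                     ifelse(n_ii > n_i, "nosZ_II", "unassigned"))
  data.frame(orf_id = rownames(counts), assigned_clade = unname(assigned),
             stringsAsFactors = FALSE)
}

#' Apply nosZ clade assignments to a labeled ORF table
#'
#' Rewrites `gene_label == "nosZ"` rows to nosZ_I / nosZ_II / unassigned
#' according to [split_nosz()] votes; nosZ ORFs absent from the hit table
#' become unassigned.
#'
#' @param orfs labeled ORF table (see [label_genes()]).
#' @param hits nosZ hit table (see [split_nosz()]).
#' @return `orfs` with clade-resolved `gene_label`.
#' @export
resolve_nosz <- function(orfs, hits) {
  stopifnot("gene_label" %in% names(orfs))
  assign <- split_nosz(hits)
  idx <- which(!is.na(orfs$gene_label) & orfs$gene_label == "nosZ")
  m <- match(orfs$orf_id[idx], assign$orf_id)
  orfs$gene_label[idx] <- ifelse(is.na(m), "unassigned",
                                 assign$assigned_clade[m])
  orfs
}

# Extract a rank from a "p__Proteobacteria;c__Gammaproteobacteria;..." style
# lineage; lineages lacking the rank pool into "unclassified bacteria".
.lineage_rank <- function(lineage, rank = c("phylum", "class")) {
  rank <- match.arg(rank)
  tag <- if (rank == "phylum") "p__" else "c__"
  out <- vapply(strsplit(lineage, ";", fixed = TRUE), function(parts) {
    hit <- grep(tag, parts, fixed = TRUE, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    val <- trimws(sub(tag, "", hit[1], fixed = TRUE))
    if (nzchar(val)) val else NA_character_
  }, character(1))
  ifelse(is.na(out), "unclassified bacteria", out)
}

#' Aggregate gene TPM by taxon
#'
#' Sums TPM per sample, gene label and taxon at the requested rank and
#' computes each taxon's percentage of that gene's total TPM. Lineages with
#' no rank annotation pool into the first-class bucket
#' `"unclassified bacteria"`. Percentages sum to 100 per sample x gene
#' whenever the gene has any TPM.
#'
#' @param orfs ORF table with `tpm`, `gene_label`, `taxon_lineage` columns.
#' @param rank `"phylum"` or `"class"`.
#' @return long data.frame `sample_id`, `gene_label`, `taxon`, `tpm`,
#'   `relative_pct`.
#' @export
aggregate_by_taxon <- function(orfs, rank = c("phylum", "class")) {
  rank <- match.arg(rank)
  stopifnot(all(c("sample_id", "gene_label", "taxon_lineage", "tpm") %in%
                  names(orfs)))
  keep <- orfs[!is.na(orfs$gene_label), ]
  if (nrow(keep) == 0) {
    return(data.frame(sample_id = character(), gene_label = character(),
                      taxon = character(), tpm = numeric(),
                      relative_pct = numeric()))
  }
  keep$taxon <- .lineage_rank(keep$taxon_lineage, rank)
  agg <- stats::aggregate(tpm ~ sample_id + gene_label + taxon, data = keep,
                          FUN = sum)
  tot <- stats::ave(agg$tpm, agg$sample_id, agg$gene_label, FUN = sum)
  agg$relative_pct <- ifelse(tot > 0, 100 * agg$tpm / tot, NA_real_)
  agg <- agg[order(agg$sample_id, agg$gene_label, -agg$tpm), ]
  rownames(agg) <- NULL
  agg
}

#' Gene-by-taxon TPM matrix with N2O production/reduction imbalance flags
#'
#' Builds a taxa x genes matrix of mean TPM (averaged over samples) for the
#' denitrification genes and flags taxa whose NO-reductase gene norB is
#' present while nitrous-oxide reductase (nosZ I + II) is absent or below a
#' configurable fraction of the norB TPM — the truncated-denitrifier
#' signature that marks net N2O producers.
#'
#' @param profile long profile from [aggregate_by_taxon()].
#' @param genes gene labels to include as columns.
#' @param imbalance_fraction flag when nosZ_I + nosZ_II TPM < this fraction
#'   of norB TPM (default 0.1).
#' @return list with `matrix` (taxa x genes) and `flags` (named logical,
#'   TRUE = norB-without-nosZ imbalance).
#' @export
gene_taxon_matrix <- function(profile, genes = DENIT_GENES,
                              imbalance_fraction = 0.1) {
  stopifnot(all(c("gene_label", "taxon", "tpm") %in% names(profile)))
  keep <- profile[profile$gene_label %in% genes, ]
  n_samples <- max(1L, length(unique(profile$sample_id)))
  taxa <- sort(unique(keep$taxon))
  mat <- matrix(0, length(taxa), length(genes),
                dimnames = list(taxa, genes))
  if (nrow(keep) > 0) {
    agg <- stats::aggregate(tpm ~ taxon + gene_label, data = keep, FUN = sum)
    mat[cbind(agg$taxon, agg$gene_label)] <- agg$tpm / n_samples
  }
  nosz <- mat[, intersect(c("nosZ_I", "nosZ_II"), genes), drop = FALSE]
  nosz_tot <- rowSums(nosz)
  norb <- if ("norB" %in% genes) mat[, "norB"] else rep(0, length(taxa))
  flags <- norb > 0 & nosz_tot < imbalance_fraction * norb
  list(matrix = mat, flags = flags)
}

#' Full ORF-table profiling chain
#'
#' Convenience wrapper: KO labeling, TPM normalization, nosZ clade
#' resolution, phylum aggregation, and the gene-by-taxon imbalance matrix.
#'
#' @param orfs raw ORF table (`orf_id`, `sample_id`, `ko_id`,
#'   `taxon_lineage`, `length_bp`, `read_count`).
#' @param nosz_hits nosZ top-hit table for [split_nosz()]; NULL leaves nosZ
#'   unsplit.
#' @param rank aggregation rank.
#' @param ko_map KO -> gene label map.
#' @return list with `orfs` (labeled, TPM), `profile`, `matrix`, `flags`.
#' @export
profile_orfs <- function(orfs, nosz_hits = NULL, rank = "phylum",
                         ko_map = DENIT_KO_MAP) {
  orfs <- label_genes(orfs, ko_map)
  orfs <- compute_tpm(orfs)
  if (!is.null(nosz_hits)) orfs <- resolve_nosz(orfs, nosz_hits)
  profile <- aggregate_by_taxon(orfs, rank = rank)
  gtm <- gene_taxon_matrix(profile)
  list(orfs = orfs, profile = profile, matrix = gtm$matrix, flags = gtm$flags)
}
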