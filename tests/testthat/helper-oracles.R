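# Independent oracles shared across tests.

# Delta-method standard error of the 29N2/30N2 count ratio from a multinomial
# draw of n pairs with 15N atom fraction f: p29 = 2f(1-f), p30 = f^2.
ratio_29_30_se <- function(n, f) {
  p29 <- 2 * f * (1 - f)
  p30 <- f^2
  r <- p29 / p30
  v29 <- n * p29 * (1 - p29)
  v30 <- n * p30 * (1 - p30)
  cov2930 <- -n * p29 * p30
  sqrt((v29 + r^2 * v30 - 2 * r * cov2930) / (n * p30)^2)
}

# Build a minimal ORF table whose per-taxon TPM shares for one gene are the
# given proportions exactly (one ORF per taxon, counts chosen so that
# count/length is proportional to the share).
orf_fixture_with_shares <- function(shares, gene_ko = "K02567",
                                    sample_id = "S1") {
  stopifnot(abs(sum(shares) - 1) < 1e-12, !is.null(names(shares)))
  n <- length(shares)
  lengths <- seq(500, by = 250, length.out = n)
  data.frame(
    orf_id = sprintf("orf%02d", seq_len(n)),
    sample_id = sample_id,
    ko_id = gene_ko,
    taxon_lineage = paste0("d__Bacteria;p__",
                           ifelse(names(shares) == "unclassified bacteria",
                                  "", names(shares))),
    length_bp = lengths,
    read_count = shares * lengths * 1000)
}

# A strictly monotone pair of length 7 whose Spearman rho is 22/28 = 0.7857
# (sum of squared rank differences 12).
rho786_xy <- function() {
  list(x = 1:7, y = c(3, 1, 2, 6, 4, 5, 7))
}
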