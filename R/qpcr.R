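# qPCR absolute quantification: standard curves with acceptance gates,
# copy-number back-calculation, abundance ratios, and exact-permutation
# Spearman correlation for small sample sets.

#' Fit a qPCR standard curve
#'
#' Least-squares line Cq ~ log10(copies) over a dilution series.
#' Amplification efficiency is 100 (10^(-1/slope) - 1); the curve passes the
#' acceptance gates when efficiency lies in [90, 110] % and R^2 >= 0.97.
#' Gated-out curves are returned with `passed = FALSE` so downstream
#' quantification can refuse them explicitly.
#'
#' @param log10_copies log10 template copies of each standard.
#' @param cq observed quantification cycles.
#' @param efficiency_gate acceptance window for efficiency (percent).
#' @param r2_gate minimum R^2.
#' @return object of class `standard_curve` with `slope`, `intercept`,
#'   `r_squared`, `efficiency_pct`, `passed`.
#' @export
fit_standard_curve <- function(log10_copies, cq,
                               efficiency_gate = c(90, 110), r2_gate = 0.97) {
  stopifnot(length(log10_copies) == length(cq))
  if (length(unique(log10_copies)) < 3) {
    stop("need at least 3 distinct dilution levels", call. = FALSE)
  }
  fit <- stats::lm(cq ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) {
    stop("standard-curve slope must be negative (Cq decreases with template)",
         call. = FALSE)
  }
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((cq - mean(cq))^2)
  eff <- 100 * (10^(-1 / slope) - 1)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, efficiency_pct = eff,
                 passed = eff >= efficiency_gate[1] & eff <= efficiency_gate[2] &
                   r2 >= r2_gate),
            class = "standard_curve")
}

#' Absolute quantification from Cq
#'
#' copies = 10^((Cq - intercept) / slope), scaled by the dilution factor and
#' divided by the extracted soil mass to give copies per gram. Refuses
#' standard curves that failed the acceptance gates.
#'
#' @param cq observed Cq value(s).
#' @param curve a [fit_standard_curve()] result.
#' @param dilution_factor fold dilution between extract and reaction.
#' @param mass_g grams of soil behind the extract aliquot.
#' @param allow_failed_curve set TRUE to override the gate refusal.
#' @return copies per gram of soil.
#' @export
quantify_copies <- function(cq, curve, dilution_factor = 1, mass_g = 1,
                            allow_failed_curve = FALSE) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!curve$passed && !allow_failed_curve) {
    stop("standard curve failed the efficiency/R^2 gates; refusing to quantify",
         call. = FALSE)
  }
  if (any(mass_g <= 0)) stop("mass_g must be > 0", call. = FALSE)
  10^((cq - curve$intercept) / curve$slope) * dilution_factor / mass_g
}

#' Per-sample denitrification gene abundance ratios
#'
#' Computes nirS/nirK, nosZ_II/nosZ_I and nir/nosZ (with nir = nirS + nirK
#' and nosZ = nosZ_I + nosZ_II) per sample, plus across-sample mean and SD.
#' Ratios with a zero denominator are reported as NA with a warning.
#'
#' @param abundances data.frame with columns `sample_id`, `gene` (one of
#'   16S, nirS, nirK, nosZ_I, nosZ_II) and `copies_per_g`.
#' @return list with `per_sample` (data.frame of ratios) and `summary`
#'   (mean/sd per ratio).
#' @export
abundance_ratios <- function(abundances) {
  stopifnot(is.data.frame(abundances),
            all(c("sample_id", "gene", "copies_per_g") %in% names(abundances)))
  wide <- stats::reshape(
    abundances[, c("sample_id", "gene", "copies_per_g")],
    idvar = "sample_id", timevar = "gene", direction = "wide")
  names(wide) <- sub("^copies_per_g\\.", "", names(wide))
  get <- function(g) if (g %in% names(wide)) wide[[g]] else {
    rep(NA_real_, nrow(wide))
  }
  nir <- get("nirS") + get("nirK")
  nos <- get("nosZ_I") + get("nosZ_II")
  safe_div <- function(num, den) ifelse(!is.na(den) & den > 0, num / den,
                                        NA_real_)
  per <- data.frame(sample_id = wide$sample_id,
                    nirS_nirK = safe_div(get("nirS"), get("nirK")),
                    nosZII_nosZI = safe_div(get("nosZ_II"), get("nosZ_I")),
                    nir_nosZ = safe_div(nir, nos))
  if (anyNA(per[, -1])) {
    warning("some ratios undefined (missing gene or zero denominator)",
            call. = FALSE)
  }
  smry <- data.frame(
    ratio = c("nirS_nirK", "nosZII_nosZI", "nir_nosZ"),
    mean = vapply(per[, -1, drop = FALSE], mean, numeric(1), na.rm = TRUE),
    sd = vapply(per[, -1, drop = FALSE], stats::sd, numeric(1), na.rm = TRUE),
    row.names = NULL)
  list(per_sample = per, summary = smry)
}

# All permutations of 1..n (n! rows); recursion is fine for the n <= 9 the
# exact test allows.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Spearman rank correlation with exact-permutation p-value
#'
#' Spearman rho with a two-sided p-value. For n <= `exact_max` the p-value is
#' exact: all n! permutations of one ranking are enumerated and
#' p = P(|rho_perm| >= |rho_obs|). For larger n the t approximation of
#' [stats::cor.test()] is used. No multiple-testing correction is applied.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param exact_max largest n for which the full enumeration runs
#'   (default 9; 9! = 362880 permutations).
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
rank_correlation <- function(x, y, exact_max = 9) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant vector; correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, method = "none"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (n <= exact_max) {
    rx <- rank(x)
    ry <- rank(y)
    perms <- .permutations(n)
    # rho for every permutation of the y ranking against the fixed x ranking
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p_val <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    p_val <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)$p.value)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p_val, n = n, method = method)
}
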