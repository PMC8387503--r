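#' Convert an isotope ratio to delta notation
#'
#' Expresses a heavy/light isotope ratio as the per-mil deviation from an
#' international standard (VPDB for carbon, atmospheric N2 for nitrogen):
#' `delta = (R_sample / R_standard - 1) * 1000`.
#'
#' @param r_sample sample isotope ratio (>= 0).
#' @param r_standard standard isotope ratio (> 0).
#' @return delta value in per mil.
#' @export
ratio_to_delta <- function(r_sample, r_standard) {
  if (any(r_standard <= 0)) stop("ratio_to_delta(): r_standard must be > 0")
  if (any(r_sample < 0)) stop("ratio_to_delta(): r_sample must be >= 0")
  (r_sample / r_standard - 1) * 1000
}

#' Convert a delta value back to an isotope ratio
#'
#' Algebraic inverse of [ratio_to_delta()].
#'
#' @param delta per-mil delta value.
#' @param r_standard standard isotope ratio (> 0).
#' @return sample isotope ratio.
#' @export
delta_to_ratio <- function(delta, r_standard) {
  if (any(r_standard <= 0)) stop("delta_to_ratio(): r_standard must be > 0")
  (delta / 1000 + 1) * r_standard
}

#' Define a tracer correction model
#'
#' Mathematical corrections for preservation and lipid-extraction effects on
#' tissue isotope values. Coefficients are study-specific and must be
#' supplied by the user (published values exist for cetacean skin and for
#' regional fish muscle); with all-zero defaults a warning reminds the user
#' that no correction is applied. Each effect is either additive
#' (`corrected = raw + offset`) or linear (`corrected = intercept +
#' slope * raw`).
#'
#' @param tissue tissue label the model applies to (e.g. `"skin"`,
#'   `"muscle"`); samples carrying a different tissue are left untouched.
#' @param lipid_d15N correction for the lipid-extraction effect on d15N:
#'   a single offset, or `c(intercept, slope)` for a linear model.
#' @param dmso_d13C,dmso_d15N corrections for DMSO preservation, same forms.
#' @return object of class `correction_model`.
#' @export
correction_model <- function(tissue = "skin",
                             lipid_d15N = 0,
                             dmso_d13C = 0,
                             dmso_d15N = 0) {
  as_eff <- function(x, name) {
    if (!is.numeric(x) || !all(is.finite(x)) || !length(x) %in% 1:2)
      stop("correction_model(): '", name, "' must be 1 (offset) or 2 ",
           "(intercept, slope) finite numbers")
    if (length(x) == 1) c(intercept = x, slope = 1) else
      c(intercept = x[1], slope = x[2])
  }
  m <- structure(list(
    tissue = tissue,
    lipid_d15N = as_eff(lipid_d15N, "lipid_d15N"),
    dmso_d13C = as_eff(dmso_d13C, "dmso_d13C"),
    dmso_d15N = as_eff(dmso_d15N, "dmso_d15N")
  ), class = "correction_model")
  if (all(vapply(m[-1], function(e) identical(unname(e), c(0, 1)), TRUE)))
    warning("correction_model(): all coefficients are identity; no ",
            "correction will be applied. Supply study-specific values.")
  m
}

apply_effect <- function(x, eff) eff[["intercept"]] + eff[["slope"]] * x

#' Apply preservation and lipid corrections to tracer measurements
#'
#' Applies a [correction_model()] to a table of isotope measurements. The
#' lipid correction fires for rows with `lipid_extracted == TRUE`, the DMSO
#' corrections for rows with `preservation == "DMSO"`; rows with a different
#' tissue are untouched. Provenance columns (`corr_lipid`, `corr_dmso`)
#' record which corrections fired, and re-applying a model to an already
#' corrected table is an error so a correction can never fire twice.
#'
#' @param samples data frame with columns `d13C`, `d15N`, and optionally
#'   `tissue`, `lipid_extracted`, `preservation`.
#' @param model a [correction_model()].
#' @return corrected copy of `samples` with provenance columns.
#' @export
apply_corrections <- function(samples, model) {
  stopifnot(inherits(model, "correction_model"), is.data.frame(samples))
  if (!all(c("d13C", "d15N") %in% names(samples)))
    stop("apply_corrections(): samples need d13C and d15N columns")
  if (!is.null(attr(samples, "corrections_applied")))
    stop("apply_corrections(): corrections already applied to this table ",
         "(idempotence guard)")
  out <- samples
  tissue_ok <- if ("tissue" %in% names(out)) out$tissue == model$tissue
               else rep(TRUE, nrow(out))
  lip <- tissue_ok & if ("lipid_extracted" %in% names(out))
    isTRUE_vec(out$lipid_extracted) else rep(TRUE, nrow(out))
  dms <- tissue_ok & if ("preservation" %in% names(out))
    out$preservation == "DMSO" else rep(FALSE, nrow(out))
  out$d15N[lip] <- apply_effect(out$d15N[lip], model$lipid_d15N)
  out$d13C[dms] <- apply_effect(out$d13C[dms], model$dmso_d13C)
  out$d15N[dms] <- apply_effect(out$d15N[dms], model$dmso_d15N)
  out$corr_lipid <- lip
  out$corr_dmso <- dms
  attr(out, "corrections_applied") <- model$tissue
  if (!any(lip | dms))
    message("apply_corrections(): model not applicable to any row")
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Default extended dietary fatty acid subset
#'
#' Fatty acids deposited in predator tissue largely unmodified from the diet
#' are the informative subset for qualitative diet comparison. The shipped
#' default list (39 names in C:DnX shorthand) is editable:
#' point `file` at any one-name-per-line text file to use a lab-specific
#' list.
#'
#' @param file path to a plain-text FA name list.
#' @return character vector of FA names.
#' @export
extended_dietary_fas <- function(file = system.file("extdata",
                                                    "extended_dietary_fa_default.txt",
                                                    package = "trophoniche")) {
  x <- readLines(file, warn = FALSE)
  x <- trimws(x[nzchar(trimws(x)) & !startsWith(trimws(x), "#")])
  x
}

#' Restrict fatty acid profiles to a subset and renormalize
#'
#' Keeps only the named FAs and rescales each profile to 100 mass percent,
#' preserving within-subset relative proportions. FAs named in `subset` but
#' absent from the table are zero-filled; the number of fills is reported as
#' an attribute and a warning.
#'
#' @param profiles data frame or matrix, one profile per row, one column per
#'   FA (mass percent). Non-FA id columns may be excluded via `id_cols`.
#' @param subset character vector of FA names to keep.
#' @param id_cols names of columns to carry through unchanged.
#' @return renormalized profiles over `subset` (plus `id_cols`), with
#'   attribute `n_zero_filled`.
#' @export
select_fa_subset <- function(profiles, subset, id_cols = intersect("id", colnames(profiles))) {
  if (length(subset) == 0) stop("select_fa_subset(): empty subset")
  profiles <- as.data.frame(profiles)
  ids <- profiles[, id_cols, drop = FALSE]
  missing_fa <- setdiff(subset, colnames(profiles))
  if (length(missing_fa))
    warning("select_fa_subset(): ", length(missing_fa),
            " FA(s) absent from the table were zero-filled")
  mat <- matrix(0, nrow(profiles), length(subset),
                dimnames = list(rownames(profiles), subset))
  have <- intersect(subset, colnames(profiles))
  mat[, have] <- as.matrix(profiles[, have, drop = FALSE])
  if (any(mat < 0)) stop("select_fa_subset(): negative mass percent")
  tot <- rowSums(mat)
  if (any(tot <= 0))
    stop("select_fa_subset(): a profile is all zero over the subset")
  out <- cbind(ids, as.data.frame(mat / tot * 100, check.names = FALSE))
  attr(out, "n_zero_filled") <- length(missing_fa) * nrow(profiles)
  out
}

#' Sum of the major essential fatty acids
#'
#' Total mass percent of 20:5n3 (EPA), 22:6n3 (DHA) and 20:4n6 (ARA), the
#' physiologically essential FAs tracked through time in blubber. Missing
#' FAs contribute zero.
#'
#' @param profiles data frame or matrix of FA mass percents (one row per
#'   sample), or a single named numeric vector.
#' @return numeric vector of sums.
#' @export
essential_fa_sum <- function(profiles) {
  keys <- c("20:5n3", "22:6n3", "20:4n6")
  if (is.numeric(profiles) && !is.matrix(profiles)) {
    return(sum(profiles[intersect(keys, names(profiles))]))
  }
  profiles <- as.data.frame(profiles)
  have <- intersect(keys, colnames(profiles))
  if (length(have) == 0) return(rep(0, nrow(profiles)))
  unname(rowSums(as.matrix(profiles[, have, drop = FALSE])))
}
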