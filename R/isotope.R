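# Lipid normalization of plasma delta13C from C:N mass ratios.
# Per-pair differences are delipidated-minus-raw:
#   d_delta13C = delta13C_del - delta13C_raw
#   d_CN       = C:N_del - C:N_raw
# and an OLS regression of d_delta13C on d_CN gives the species slope m and
# intercept c. For raw-only samples the C:N excess term is
# mean(C:N_del) - C:N_raw, so lipid-rich raw samples receive a negative
# excess; with the (typically negative) fitted slope the correction added
# back is positive, as lipids depress delta13C.

#' Fit a species lipid-normalization model
#'
#' @param pairs data.frame with columns `d13c_raw`, `d13c_del`, `cn_raw`,
#'   `cn_del` (one row per sample measured both ways); rows with any of the
#'   four missing are dropped.
#' @param species Species label stored with the model.
#' @param form `"direct"`: correction = `m * dCN + c` (the regression
#'   prediction; default). `"printed-inverse"`: correction = `(dCN + c) / m`,
#'   an alternative algebraic form kept behind this switch.
#' @return Object of class `normalization_model`: `species`, `m`, `c`,
#'   `mean_cn_del`, `n`, `form`.
#' @examples
#' p <- data.frame(d13c_raw = c(-22.6, -21.9, -21.2),
#'                 d13c_del = c(-22.0, -21.8, -21.0),
#'                 cn_raw = c(4.5, 3.6, 3.9), cn_del = c(3.5, 3.5, 3.3))
#' fit_normalization(p, "wandering")
#' @export
fit_normalization <- function(pairs, species = "unknown",
                              form = c("direct", "printed-inverse")) {
  form <- match.arg(form)
  need <- c("d13c_raw", "d13c_del", "cn_raw", "cn_del")
  if (!all(need %in% names(pairs)))
    stop("fit_normalization: pairs must have ", paste(need, collapse = ", "),
         call. = FALSE)
  ok <- stats::complete.cases(pairs[need])
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 3)
    stop("fit_normalization: need at least 3 complete raw/delipidated pairs",
         call. = FALSE)
  dd <- pairs$d13c_del - pairs$d13c_raw
  dcn <- pairs$cn_del - pairs$cn_raw
  if (stats::var(dcn) == 0)
    stop("fit_normalization: zero variance in C:N differences (singular fit)",
         call. = FALSE)
  fit <- stats::lm(dd ~ dcn)
  structure(list(species = species,
                 m = unname(stats::coef(fit)[2]),
                 c = unname(stats::coef(fit)[1]),
                 mean_cn_del = mean(pairs$cn_del),
                 n = nrow(pairs), form = form),
            class = "normalization_model")
}

#' @export
print.normalization_model <- function(x, ...) {
  cat(sprintf(
    "normalization_model [%s, %s form]: m = %.4f, c = %.4f permil, mean C:N_del = %.3f (n = %d)\n",
    x$species, x$form, x$m, x$c, x$mean_cn_del, x$n))
  invisible(x)
}

#' Lipid-correct the delta13C of a raw-only plasma sample
#'
#' The C:N excess of the raw sample is `mean(C:N_del) - C:N_raw`; the
#' correction follows the model's form and is added to the raw delta13C.
#' Samples that already have a delipidated measurement are refused (use the
#' measured value). delta15N is never altered by lipid handling.
#'
#' @param sample One-row data.frame with `d13c_raw`, `cn_raw`, optionally
#'   `d13c_del` and `species`.
#' @param model A [fit_normalization()] model for the sample's species.
#' @return Corrected delta13C, permil.
#' @export
correct_delta13c <- function(sample, model) {
  stopifnot(inherits(model, "normalization_model"))
  if (!is.na(sample$d13c_del %||% NA))
    stop("correct_delta13c: sample already has a delipidated measurement",
         call. = FALSE)
  if (!is.null(sample$species) && !is.na(sample$species) &&
      model$species != "unknown" && sample$species != model$species)
    stop("correct_delta13c: model fitted for species '", model$species,
         "', sample is '", sample$species, "'", call. = FALSE)
  dcn <- model$mean_cn_del - sample$cn_raw
  dd <- if (model$form == "direct") model$m * dcn + model$c
  else {
    if (model$m == 0)
      stop("correct_delta13c: printed-inverse form needs nonzero slope",
           call. = FALSE)
    (dcn + model$c) / model$m
  }
  sample$d13c_raw + dd
}

#' Flag lipid-rich plasma by C:N mass ratio
#'
#' @param cn_raw C:N mass ratio(s) of raw plasma.
#' @return Logical: `TRUE` iff C:N strictly exceeds 3.5, the conventional
#'   lipid-richness cutoff for aquatic animal tissue.
#' @export
flag_high_lipid <- function(cn_raw) {
  if (any(!is.finite(cn_raw))) stop("flag_high_lipid: C:N missing",
                                    call. = FALSE)
  cn_raw > 3.5
}
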