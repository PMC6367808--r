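#' Anthocyanin content by the pH-differential method
#'
#' Monomeric anthocyanin content from paired absorbance readings at 510 and
#' 700 nm in pH 1.0 and pH 4.5 buffers:
#'
#' `content (mg/g FW) = dA * dilution * volume_l * 1000 * mw / (epsilon * mass_g)`
#'
#' with `dA = (A510 - A700)[pH 1.0] - (A510 - A700)[pH 4.5]`. The defaults
#' are the constants of a 5x dilution of a 5-mL extract of 0.5 g peel,
#' quantified as cyanidin-3-glucoside (MW 449.2 g/mol, molar absorptivity
#' 26,900 L/mol/cm), i.e. the factor `dA * 5 * 0.005 * 1000 * 449.2 /
#' (26900 * 0.5)`. A negative `dA` (measurement noise) yields a negative
#' value with a warning rather than silent clamping.
#'
#' @param a510_ph1,a700_ph1,a510_ph45,a700_ph45 Absorbances (vectorised).
#' @param dilution Dilution factor (default 5).
#' @param volume_l Extract volume in litres (default 0.005).
#' @param mw Molecular weight of the reference anthocyanin, g/mol
#'   (default 449.2).
#' @param epsilon Molar absorptivity, L/mol/cm (default 26900).
#' @param mass_g Fresh sample mass in grams (default 0.5).
#' @return Anthocyanin content in mg per g fresh weight.
#' @export
anthocyanin_content <- function(a510_ph1, a700_ph1, a510_ph45, a700_ph45,
                                dilution = 5, volume_l = 0.005, mw = 449.2,
                                epsilon = 26900, mass_g = 0.5) {
  vals <- c(a510_ph1, a700_ph1, a510_ph45, a700_ph45)
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    stop("domain error: absorbances must be finite numbers", call. = FALSE)
  }
  da <- (a510_ph1 - a700_ph1) - (a510_ph45 - a700_ph45)
  if (any(da < 0)) {
    warning(sprintf("%d negative delta-A value(s): likely measurement noise",
                    sum(da < 0)), call. = FALSE)
  }
  da * dilution * volume_l * 1000 * mw / (epsilon * mass_g)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-[(Ct_target,sample - Ct_reference,sample) -
#' (Ct_target,control - Ct_reference,control)]`: the qPCR fold change of a
#' target gene in a sample relative to a control condition, each normalised
#' to a reference gene. Shift-invariant in Ct (adding a constant to every Ct
#' leaves the result unchanged).
#'
#' @param ct_target_sample,ct_reference_sample Ct of target and reference
#'   gene in the sample of interest.
#' @param ct_target_control,ct_reference_control Ct of target and reference
#'   gene in the control/calibrator.
#' @return Fold change (vectorised).
#' @export
relative_expression <- function(ct_target_sample, ct_reference_sample,
                                ct_target_control, ct_reference_control) {
  vals <- c(ct_target_sample, ct_reference_sample,
            ct_target_control, ct_reference_control)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop("domain error: Ct values must be positive finite numbers", call. = FALSE)
  }
  ddct <- (ct_target_sample - ct_reference_sample) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Batch assay computation with replicate summaries
#'
#' Applies [anthocyanin_content()] or [relative_expression()] row-wise to a
#' table of readings and summarises replicates (mean, SD, n) per group.
#'
#' @param x `data.frame` of readings. For `assay = "anthocyanin"` it needs
#'   columns a510_ph1, a700_ph1, a510_ph45, a700_ph45; for `assay = "ddct"`,
#'   ct_target_sample, ct_reference_sample, ct_target_control,
#'   ct_reference_control. An optional `group` column defines replicate
#'   groups (default: one group).
#' @param assay Which formula to apply.
#' @param ... Passed to the assay function (e.g. alternative constants).
#' @return List: `values` (input with a `value` column) and `summary`
#'   (per-group mean, sd, n).
#' @export
assay_batch <- function(x, assay = c("anthocyanin", "ddct"), ...) {
  assay <- match.arg(assay)
  dt <- as.data.table(x)
  cols <- if (assay == "anthocyanin") {
    c("a510_ph1", "a700_ph1", "a510_ph45", "a700_ph45")
  } else {
    c("ct_target_sample", "ct_reference_sample",
      "ct_target_control", "ct_reference_control")
  }
  if (!all(cols %in% names(dt))) {
    stop(sprintf("batch table needs columns: %s", paste(cols, collapse = ", ")),
         call. = FALSE)
  }
  fn <- if (assay == "anthocyanin") anthocyanin_content else relative_expression
  dt[, value := do.call(fn, c(unname(as.list(.SD)), list(...))), .SDcols = cols]
  if (!"group" %in% names(dt)) dt[, group := "all"]
  summary <- dt[, .(mean = mean(value), sd = sd(value), n = .N), by = group]
  list(values = dt[], summary = summary)
}
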