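#' Variance components of a repeated-digitalisation design
#'
#' Decomposes the variance of one shape parameter measured over a crossed
#' cartilage x operator x digitalisation design into four additive
#' components:
#' \deqn{\sigma^2_{total} = \sigma^2_{cartilage} + \sigma^2_{operator} +
#'   \sigma^2_{digitalisation} + \sigma^2_{residual}}
#'
#' Two estimation paths are available. For balanced designs the default
#' closed-form expected-mean-squares (EMS) path equates the ANOVA mean
#' squares of the crossed main-effects model to their expectations; negative
#' raw estimates are truncated to zero before summing. For unbalanced data a
#' restricted-maximum-likelihood path (`lme4::lmer` with three crossed random
#' intercepts) is available; for balanced data with interior estimates the
#' two coincide.
#'
#' @param data Long-format measurement table with columns `cartilage_id`,
#'   `operator_id`, `digitalisation` and `value` (plus `parameter` when
#'   `parameter` is given).
#' @param parameter Optional parameter name to filter `data$parameter` on.
#' @param method `"ems"` (closed form, balanced designs) or `"reml"`.
#' @return An object of class `variance_components`: the four components,
#'   `sigma2_total` (their exact sum), `raw` (untruncated estimates),
#'   `method` and `n`.
#' @export
estimate_variance_components <- function(data, parameter = NULL,
                                         method = c("ems", "reml")) {
  method <- match.arg(method)
  if (!is.null(parameter)) {
    if (!"parameter" %in% names(data)) {
      abort_contract("`data` has no `parameter` column to filter on.")
    }
    data <- data[data$parameter == parameter, , drop = FALSE]
  }
  required <- c("cartilage_id", "operator_id", "digitalisation", "value")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort_contract(sprintf("Measurement table is missing column(s): %s.",
                           paste(missing, collapse = ", ")))
  }
  cart <- factor(data$cartilage_id)
  oper <- factor(data$operator_id)
  digi <- factor(data$digitalisation)
  if (nlevels(cart) < 2 || nlevels(oper) < 2 || nlevels(digi) < 2) {
    abort_contract("Each factor needs at least 2 levels.")
  }
  value <- data$value
  balanced <- length(unique(table(cart, oper, digi))) == 1 &&
    all(table(cart, oper, digi) > 0)

  if (method == "ems") {
    if (!balanced) {
      abort_contract(paste(
        "The closed-form EMS path requires a balanced design;",
        "use method = \"reml\" for unbalanced data."
      ))
    }
    nrep <- unname(table(cart, oper, digi)[1])
    nc <- nlevels(cart); no <- nlevels(oper); nd <- nlevels(digi)
    fit <- stats::aov(value ~ cart + oper + digi)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    names(ms) <- trimws(rownames(summary(fit)[[1]]))
    ms_res <- ms[["Residuals"]]
    raw <- c(
      cartilage = (ms[["cart"]] - ms_res) / (no * nd * nrep),
      operator = (ms[["oper"]] - ms_res) / (nc * nd * nrep),
      digitalisation = (ms[["digi"]] - ms_res) / (nc * no * nrep),
      residual = ms_res
    )
  } else {
    df <- data.frame(value = value, cart = cart, oper = oper, digi = digi)
    fit <- lme4::lmer(
      value ~ 1 + (1 | cart) + (1 | oper) + (1 | digi),
      data = df, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE,
                                  optCtrl = list(xtol_abs = 1e-12,
                                                 ftol_abs = 1e-12))
    )
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(g) vc$vcov[match(g, vc$grp)]
    raw <- c(cartilage = get("cart"), operator = get("oper"),
             digitalisation = get("digi"), residual = get("Residual"))
  }
  comp <- pmax(raw, 0)
  structure(
    list(
      sigma2_cartilage = comp[["cartilage"]],
      sigma2_operator = comp[["operator"]],
      sigma2_digitalisation = comp[["digitalisation"]],
      sigma2_residual = comp[["residual"]],
      sigma2_total = sum(comp),
      raw = raw, method = method, n = length(value)
    ),
    class = "variance_components"
  )
}

#' Construct variance components directly
#'
#' Builds a `variance_components` object from known (or hypothesised)
#' component values, e.g. for plug-in ICC computations.
#'
#' @param cartilage,operator,digitalisation,residual Non-negative variances
#'   in squared parameter units.
#' @return An object of class `variance_components`.
#' @export
variance_components <- function(cartilage, operator, digitalisation, residual) {
  comp <- c(cartilage = cartilage, operator = operator,
            digitalisation = digitalisation, residual = residual)
  if (any(!is.finite(comp)) || any(comp < 0)) {
    abort_contract("Variance components must be finite and non-negative.")
  }
  structure(
    list(sigma2_cartilage = comp[["cartilage"]],
         sigma2_operator = comp[["operator"]],
         sigma2_digitalisation = comp[["digitalisation"]],
         sigma2_residual = comp[["residual"]],
         sigma2_total = sum(comp), raw = comp, method = "plug-in", n = NA_integer_),
    class = "variance_components"
  )
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> (%s) cartilage %.4g, operator %.4g, digitalisation %.4g, residual %.4g; total %.4g\n",
    x$method, x$sigma2_cartilage, x$sigma2_operator,
    x$sigma2_digitalisation, x$sigma2_residual, x$sigma2_total
  ))
  invisible(x)
}

check_vc <- function(vc) {
  if (!inherits(vc, "variance_components")) {
    abort_contract("Expected a `variance_components` object.")
  }
  if (!is.finite(vc$sigma2_total) || vc$sigma2_total <= 0) {
    rlang::abort("Total variance is zero; the ICC is undefined.",
                 class = "contourfit_error_undefined")
  }
  invisible(vc)
}

#' Intra-observer intraclass correlation
#'
#' The repeatability ICC from variance components: the share of total
#' variance not attributable to digitalisation-to-digitalisation variation,
#' \eqn{(\sigma^2_{total} - (\sigma^2_{digitalisation} + \sigma^2_{residual}))
#'   / \sigma^2_{total}}.
#'
#' @param vc A [variance_components()] object with positive total variance.
#' @return ICC value in (-Inf, 1].
#' @export
icc_intra <- function(vc) {
  check_vc(vc)
  (vc$sigma2_total - (vc$sigma2_digitalisation + vc$sigma2_residual)) /
    vc$sigma2_total
}

#' Inter-observer intraclass correlation
#'
#' The reproducibility ICC from variance components: the share of total
#' variance not attributable to operator-to-operator variation,
#' \eqn{(\sigma^2_{total} - (\sigma^2_{operator} + \sigma^2_{residual}))
#'   / \sigma^2_{total}}.
#'
#' @inheritParams icc_intra
#' @return ICC value in (-Inf, 1].
#' @export
icc_inter <- function(vc) {
  check_vc(vc)
  (vc$sigma2_total - (vc$sigma2_operator + vc$sigma2_residual)) /
    vc$sigma2_total
}

#' Standard error of measurement
#'
#' Absolute-reliability metric
#' \eqn{SEM = \sqrt{\sigma^2_{total} (1 - ICC)}}, in the parameter's units.
#'
#' @inheritParams icc_intra
#' @param icc An ICC value, at most 1.
#' @return SEM, same units as the parameter.
#' @export
sem_from_icc <- function(vc, icc) {
  check_vc(vc)
  if (!is.finite(icc) || icc > 1) {
    abort_contract("`icc` must be finite and at most 1.")
  }
  sqrt(vc$sigma2_total * (1 - icc))
}

#' 95% confidence half-width from a SEM
#'
#' The mean 95% confidence interval half-width, `1.96 * SEM`, reported to
#' one decimal as in published reliability tables.
#'
#' @param sem Non-negative SEM value(s), mm or degrees.
#' @return `round(1.96 * sem, 1)`.
#' @examples
#' ci95_from_sem(3.0) # 5.9
#' @export
ci95_from_sem <- function(sem) {
  if (any(!is.finite(sem)) || any(sem < 0)) {
    abort_contract("`sem` must be finite and non-negative.")
  }
  round(1.96 * sem, 1)
}

#' Qualitative ICC classification
#'
#' Classification bands for relative reliability: poor (< 0.5), moderate
#' (0.5 to 0.75), good (0.75 to 0.90) and excellent (>= 0.90); lower bounds
#' inclusive.
#'
#' @param icc Finite ICC value(s).
#' @return Character vector in `c("poor", "moderate", "good", "excellent")`.
#' @examples
#' classify_icc(c(0.68, 0.90, 0.49))
#' @export
classify_icc <- function(icc) {
  if (any(!is.finite(icc))) abort_contract("`icc` must be finite.")
  dplyr::case_when(
    icc < 0.5 ~ "poor",
    icc < 0.75 ~ "moderate",
    icc < 0.90 ~ "good",
    TRUE ~ "excellent"
  )
}

#' Qualitative SEM classification
#'
#' Classification bands for absolute reliability, shared by millimetre and
#' degree parameters: excellent (< 1), good (1 to 2), moderate (2 to 3) and
#' poor (3 or higher); lower bounds inclusive.
#'
#' @param sem Non-negative SEM value(s), mm or degrees.
#' @return Character vector in
#'   `c("excellent", "good", "moderate", "poor")`.
#' @examples
#' classify_sem(c(0.4, 3.0, 1.5))
#' @export
classify_sem <- function(sem) {
  if (any(!is.finite(sem)) || any(sem < 0)) {
    abort_contract("`sem` must be finite and non-negative.")
  }
  dplyr::case_when(
    sem < 1 ~ "excellent",
    sem < 2 ~ "good",
    sem < 3 ~ "moderate",
    TRUE ~ "poor"
  )
}

#' SEM as a percentage of a reference value
#'
#' `100 * sem / |reference|`, where the reference defaults to the parameter's
#' mean in the calling code. Expressed as a percentage to aid comparison
#' across parameters with different ranges and units.
#'
#' @param sem Non-negative SEM value(s).
#' @param reference Non-zero reference value(s), same units.
#' @return Percentage(s).
#' @export
sem_percent <- function(sem, reference) {
  if (any(!is.finite(reference)) || any(reference == 0)) {
    rlang::abort("`reference` must be finite and non-zero.",
                 class = "contourfit_error_undefined")
  }
  100 * sem / abs(reference)
}

# Unwrap angle values (degrees) to the 360-degree branch nearest their
# circular mean, so variances are not inflated by the +/-180 cut.
unwrap_angles <- function(values) {
  rad <- deg2rad(values)
  mu <- rad2deg(atan2(mean(sin(rad)), mean(cos(rad))))
  mu + wrap_angle(values - mu)
}

#' Full reliability report for a digitalisation study
#'
#' Runs the complete reliability analysis per cartilage type and parameter:
#' descriptives (mean, SD, 95% CI of the mean), variance components, intra-
#' and inter-observer ICC, SEM, %SEM (SEM relative to the absolute parameter
#' mean by default), 95% CI half-widths from the SEM, and the qualitative
#' ICC/SEM classifications. Angle parameters (unit `"deg"`) are unwrapped to
#' the branch nearest their circular mean before any statistic is computed.
#'
#' @param data Long-format measurement table with columns `cartilage_id`,
#'   `cartilage_type`, `operator_id`, `digitalisation`, `parameter`, `value`,
#'   `unit` (balanced design for the EMS path).
#' @param method Variance-component path, `"ems"` or `"reml"`.
#' @param sem_reference Optional function `function(values) -> scalar` giving
#'   the reference magnitude for %SEM; defaults to `|mean|`.
#' @return A tibble with one row per cartilage type x parameter: class
#'   `reliability_report`. `sd` is the pooled sample SD; `rms_sd`
#'   (`sqrt(sigma2_total)`) is reported separately since the two need not
#'   coincide.
#' @export
reliability_report <- function(data, method = c("ems", "reml"),
                               sem_reference = NULL) {
  method <- match.arg(method)
  required <- c("cartilage_id", "cartilage_type", "operator_id",
                "digitalisation", "parameter", "value", "unit")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort_contract(sprintf("Measurement table is missing column(s): %s.",
                           paste(missing, collapse = ", ")))
  }
  groups <- dplyr::distinct(data, .data$cartilage_type, .data$parameter,
                            .data$unit)
  rows <- purrr::pmap(groups, function(cartilage_type, parameter, unit) {
    sub <- data[data$cartilage_type == cartilage_type &
                  data$parameter == parameter, , drop = FALSE]
    values <- sub$value
    if (identical(unit, "deg")) values <- unwrap_angles(values)
    sub$value <- values
    n <- length(values)
    mu <- mean(values)
    sdev <- stats::sd(values)
    vc <- estimate_variance_components(sub, method = method)
    zero_total <- vc$sigma2_total <= 0
    iin <- if (zero_total) 1 else icc_intra(vc)
    iout <- if (zero_total) 1 else icc_inter(vc)
    s_in <- if (zero_total) 0 else sem_from_icc(vc, iin)
    s_out <- if (zero_total) 0 else sem_from_icc(vc, iout)
    ref <- if (is.null(sem_reference)) abs(mu) else abs(sem_reference(values))
    tibble::tibble(
      cartilage_type = cartilage_type, parameter = parameter, unit = unit,
      n = n, mean = mu, sd = sdev,
      ci_mean_lo = mu - 1.96 * sdev / sqrt(n),
      ci_mean_hi = mu + 1.96 * sdev / sqrt(n),
      rms_sd = sqrt(vc$sigma2_total),
      sigma2_cartilage = vc$sigma2_cartilage,
      sigma2_operator = vc$sigma2_operator,
      sigma2_digitalisation = vc$sigma2_digitalisation,
      sigma2_residual = vc$sigma2_residual,
      sigma2_total = vc$sigma2_total,
      icc_intra = iin, icc_inter = iout,
      sem_intra = s_in, sem_inter = s_out,
      sem_pct_intra = if (ref > 0) sem_percent(s_in, ref) else NA_real_,
      sem_pct_inter = if (ref > 0) sem_percent(s_out, ref) else NA_real_,
      ci95_intra = ci95_from_sem(s_in),
      ci95_inter = ci95_from_sem(s_out),
      icc_class_intra = classify_icc(iin),
      icc_class_inter = classify_icc(iout),
      sem_class_intra = classify_sem(s_in),
      sem_class_inter = classify_sem(s_out)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("reliability_report", class(out))
  out
}
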