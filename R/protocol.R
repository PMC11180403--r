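#' Thresholds for the hemodynamic treatment-decision protocol
#'
#' The decision table screens, in fixed order, preload responsiveness
#' (stroke volume variation), vasomotor tone (systemic vascular
#' resistance, with dynamic arterial elastance arbitrating whether fluid
#' alone will restore pressure) and contractility (systolic slope). The
#' cut-offs are site-configurable surrogates in the range the
#' goal-directed-therapy literature uses, not fixed constants of the
#' method.
#'
#' @param svv_high SVV above which the patient is preload-responsive, %.
#' @param eadyn_high Dynamic arterial elastance above which fluid is
#'   expected to raise pressure (dimensionless).
#' @param svr_low SVR below which vasomotor tone is deficient,
#'   dyn.s.cm^-5.
#' @param dpdtmax_low Systolic slope below which contractility is
#'   deficient, mmHg/s.
#' @return An object of class `protocol_thresholds`.
#' @export
protocol_thresholds <- function(svv_high = 13, eadyn_high = 0.9,
                                svr_low = 800, dpdtmax_low = 600) {
  th <- list(svv_high = svv_high, eadyn_high = eadyn_high,
             svr_low = svr_low, dpdtmax_low = dpdtmax_low)
  if (any(vapply(th, function(v) !is.finite(v) || v <= 0, logical(1))))
    stop("all protocol thresholds must be positive and finite", call. = FALSE)
  structure(th, class = "protocol_thresholds")
}

#' Map a hemodynamic snapshot to one of six treatment options
#'
#' Deterministic traversal of an ordered rule list: preload first (SVV),
#' then vasomotor tone (SVR, and dynamic arterial elastance within the
#' preload-positive branch), then contractility (dP/dtmax). A preload rule
#' combined with a tone or contractility rule yields the corresponding
#' combination option; no rule firing yields observation. The traversal is
#' recorded in `rationale_path` so every recommendation is auditable.
#'
#' @param inputs Named list or one-row data frame with fields `svv`,
#'   `eadyn`, `dpdtmax`, `svr` (and optionally `cardiac_index`, `map`,
#'   which the default table does not consult).
#' @param thresholds A [protocol_thresholds()].
#' @return A list of class `decision_outcome` with elements `option` (one
#'   of `fluid`, `vasopressor`, `inotrope`, `fluid_plus_vasopressor`,
#'   `fluid_plus_inotrope`, `observation`) and `rationale_path`.
#' @examples
#' recommend(list(svv = 16, eadyn = 1.1, dpdtmax = 900, svr = 1100),
#'           protocol_thresholds())
#' @export
recommend <- function(inputs, thresholds = protocol_thresholds()) {
  if (!inherits(thresholds, "protocol_thresholds"))
    stop("thresholds must be created by protocol_thresholds()", call. = FALSE)
  need <- c("svv", "eadyn", "dpdtmax", "svr")
  vals <- lapply(need, function(f) {
    v <- inputs[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("decision input '", f, "' must be a single finite number",
           call. = FALSE)
    as.numeric(v)
  })
  names(vals) <- need
  if (vals$svv < 0) stop("svv must be >= 0", call. = FALSE)

  path <- character(0)
  preload <- vals$svv > thresholds$svv_high
  path <- c(path, sprintf("preload:svv%s%g%s",
                          if (preload) ">" else "<=", thresholds$svv_high,
                          if (preload) ":fire" else ":pass"))
  tone <- vals$svr < thresholds$svr_low
  path <- c(path, sprintf("tone:svr%s%g%s",
                          if (tone) "<" else ">=", thresholds$svr_low,
                          if (tone) ":fire" else ":pass"))
  contract <- vals$dpdtmax < thresholds$dpdtmax_low
  path <- c(path, sprintf("contractility:dpdtmax%s%g%s",
                          if (contract) "<" else ">=", thresholds$dpdtmax_low,
                          if (contract) ":fire" else ":pass"))

  if (preload) {
    if (tone) {
      option <- "fluid_plus_vasopressor"
    } else {
      # fluid is pressure-effective only when arterial elastance is high
      pressure_ok <- vals$eadyn > thresholds$eadyn_high
      path <- c(path, sprintf("elastance:eadyn%s%g%s",
                              if (pressure_ok) ">" else "<=",
                              thresholds$eadyn_high,
                              if (pressure_ok) ":pass" else ":fire"))
      if (!pressure_ok) {
        option <- "fluid_plus_vasopressor"
      } else if (contract) {
        option <- "fluid_plus_inotrope"
      } else {
        option <- "fluid"
      }
    }
  } else if (tone) {
    option <- "vasopressor"
  } else if (contract) {
    option <- "inotrope"
  } else {
    option <- "observation"
  }
  structure(list(option = option, rationale_path = path),
            class = "decision_outcome")
}

#' @export
print.decision_outcome <- function(x, ...) {
  cat("Recommended option:", x$option, "\n")
  cat("Rationale:", paste(x$rationale_path, collapse = " -> "), "\n")
  invisible(x)
}

#' The six treatment options of the protocol
#' @return Character vector of option names.
#' @export
treatment_options <- function() {
  c("fluid", "vasopressor", "inotrope",
    "fluid_plus_vasopressor", "fluid_plus_inotrope", "observation")
}
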