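# Reference physiology: organ volumes, blood flows, tissue:plasma partition
# coefficients for an average 70 kg adult.  Circulatory topology: lung sits in
# series between the venous and arterial pools at cardiac output; gut and
# spleen drain into the liver (portal inflow); the hepatic artery carries the
# balance Q_liver - Q_gut - Q_spleen; all other systemic organs (and the
# liver's total outflow) return to the venous pool.

.compartment_roles <- c(
  "non-eliminating", "liver", "kidney", "arterial-blood", "venous-blood",
  "lung"
)

#' Reference adult physiology
#'
#' Returns the default 14-compartment physiology of an average 70 kg adult:
#' twelve perfused tissues plus arterial and venous blood pools. Volumes are
#' in mL, blood flows in mL/min and partition coefficients are dimensionless
#' tissue:plasma ratios (Kp). The blood pools and lung carry cardiac output
#' (6500 mL/min); blood Kp is 1 by definition.
#'
#' @return An object of class `apap_physiology`: a data frame with columns
#'   `name`, `volume_ml`, `blood_flow_ml_min`, `partition_coefficient` and
#'   `role`, and attributes `body_weight_kg` (70) and `blood_plasma_ratio`
#'   (1).
#' @seealso [validate_physiology()]
#' @examples
#' phys <- default_physiology()
#' subset(phys, name == "liver")
#' @export
default_physiology <- function() {
  comp <- data.frame(
    name = c(
      "adipose", "bone", "brain", "gut", "heart", "kidney", "liver",
      "lung", "muscle", "rest_of_body", "skin", "spleen",
      "arterial_blood", "venous_blood"
    ),
    volume_ml = c(
      8372, 5992, 1400, 1197, 329, 308, 1799,
      532, 28000, 13895, 2597, 182,
      1799, 3598
    ),
    blood_flow_ml_min = c(
      325, 325, 780, 1105, 260, 1235, 1625,
      6500, 1105, 520, 325, 130,
      6500, 6500
    ),
    partition_coefficient = c(
      0.312, 0.682, 1.05, 0.92, 0.852, 0.906, 0.93,
      0.87, 0.88, 1, 0.853, 0.915,
      1, 1
    ),
    role = c(
      "non-eliminating", "non-eliminating", "non-eliminating",
      "non-eliminating", "non-eliminating", "kidney", "liver",
      "lung", "non-eliminating", "non-eliminating", "non-eliminating",
      "non-eliminating", "arterial-blood", "venous-blood"
    ),
    stringsAsFactors = FALSE
  )
  structure(comp,
    body_weight_kg = 70,
    blood_plasma_ratio = 1,
    class = c("apap_physiology", "data.frame")
  )
}

#' Validate a physiology parameter set
#'
#' Checks structural and physical invariants of an [default_physiology()]-style
#' parameter set: positive volumes and partition coefficients, non-negative
#' flows, exactly one compartment per special role, a positive hepatic
#' arterial flow (`Q_liver - Q_gut - Q_spleen > 0`), and conservation of flow
#' (the venous returns of all systemic organs sum to cardiac output, i.e. the
#' lung flow, to a relative tolerance of 1e-9).
#'
#' @param physiology An `apap_physiology` object (a data frame as returned by
#'   [default_physiology()]).
#' @return A character vector of violation descriptions; empty when the set is
#'   valid. Violations are returned, never raised.
#' @examples
#' validate_physiology(default_physiology()) # character(0)
#' @export
validate_physiology <- function(physiology) {
  out <- character(0)
  req <- c("name", "volume_ml", "blood_flow_ml_min", "partition_coefficient",
           "role")
  if (!is.data.frame(physiology) || !all(req %in% names(physiology))) {
    return(sprintf("physiology must be a data frame with columns %s",
                   paste(req, collapse = ", ")))
  }
  p <- physiology
  bw <- attr(p, "body_weight_kg")
  bp <- attr(p, "blood_plasma_ratio")
  if (is.null(bw) || !is.finite(bw) || bw <= 0) {
    out <- c(out, "body_weight_kg attribute must be a positive number")
  }
  if (is.null(bp) || !is.finite(bp) || bp <= 0) {
    out <- c(out, "blood_plasma_ratio attribute must be a positive number")
  }
  if (anyDuplicated(p$name)) {
    out <- c(out, "compartment names must be unique")
  }
  bad_role <- setdiff(unique(p$role), .compartment_roles)
  if (length(bad_role)) {
    out <- c(out, sprintf("unknown role(s): %s",
                          paste(bad_role, collapse = ", ")))
  }
  for (r in c("liver", "kidney", "lung", "arterial-blood", "venous-blood")) {
    n <- sum(p$role == r)
    if (n != 1L) {
      out <- c(out, sprintf("exactly one compartment must have role '%s' (found %d)",
                            r, n))
    }
  }
  if (any(!is.finite(p$volume_ml) | p$volume_ml <= 0)) {
    out <- c(out, "all compartment volumes must be > 0")
  }
  if (any(!is.finite(p$blood_flow_ml_min) | p$blood_flow_ml_min < 0)) {
    out <- c(out, "all blood flows must be >= 0")
  }
  perfused <- !(p$role %in% c("arterial-blood", "venous-blood"))
  if (any(!is.finite(p$partition_coefficient[perfused]) |
            p$partition_coefficient[perfused] <= 0)) {
    out <- c(out, "partition coefficients of perfused tissues must be > 0")
  }
  if (length(out)) return(out)

  flow <- function(nm) p$blood_flow_ml_min[p$name == nm]
  q_liver <- p$blood_flow_ml_min[p$role == "liver"]
  q_lung <- p$blood_flow_ml_min[p$role == "lung"]
  q_gut <- if ("gut" %in% p$name) flow("gut") else 0
  q_spleen <- if ("spleen" %in% p$name) flow("spleen") else 0
  q_ha <- q_liver - q_gut - q_spleen
  if (q_ha <= 0) {
    out <- c(out, sprintf(
      "hepatic arterial flow Q_liver - Q_gut - Q_spleen = %g mL/min must be > 0",
      q_ha))
  }
  # Systemic venous return: every perfused organ except lung, minus the portal
  # tributaries (gut, spleen) whose outflow is already counted inside Q_liver.
  systemic <- perfused & p$role != "lung" & !(p$name %in% c("gut", "spleen"))
  q_ret <- sum(p$blood_flow_ml_min[systemic])
  if (abs(q_ret - q_lung) > 1e-9 * max(q_lung, 1)) {
    out <- c(out, sprintf(
      "venous return (%g mL/min) must equal cardiac output / lung flow (%g mL/min)",
      q_ret, q_lung))
  }
  out
}

#' @export
print.apap_physiology <- function(x, ...) {
  cat(sprintf(
    "APAP PBPK physiology: %d compartments, body weight %g kg, BP %g\n",
    nrow(x), attr(x, "body_weight_kg"), attr(x, "blood_plasma_ratio")))
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
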