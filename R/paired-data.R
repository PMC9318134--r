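# Paired measurement sets and cohort datasets with controlled statistical
# structure, used to exercise the agreement and comparison stages.

#' Construct a paired measurement set
#'
#' A paired measurement set holds one pair of area-fraction percentages per
#' subject — the two axes may be two methods (MC/DC), two observers, or two
#' timepoints (T1/T2).
#'
#' @param subject subject identifiers (unique).
#' @param value_a,value_b paired measurements, percent in \[0, 100\].
#' @param labels length-2 character vector naming the A and B axes.
#' @return A data frame of class `paired_set` with columns `subject`,
#'   `value_a`, `value_b`.
#' @export
paired_set <- function(subject, value_a, value_b, labels = c("A", "B")) {
  stopifnot(
    length(subject) == length(value_a), length(value_a) == length(value_b),
    !anyNA(value_a), !anyNA(value_b),
    all(value_a >= 0 & value_a <= 100), all(value_b >= 0 & value_b <= 100),
    length(labels) == 2L
  )
  if (anyDuplicated(subject)) stop("subject identifiers must be unique")
  structure(
    data.frame(subject = subject, value_a = value_a, value_b = value_b),
    labels = as.character(labels),
    class = c("paired_set", "data.frame")
  )
}

#' Simulate paired measurements with controlled bias and spread
#'
#' Draws base values from `base` (default: uniform on 1-30%, the sparse
#' staining range the synthetic fields use), then sets
#' `value_b = value_a + Normal(bias, sd)`. Both columns are clipped to
#' \[0, 100\]; the number of clipped values is recorded in the `n_clipped`
#' attribute.
#'
#' @param n number of pairs (>= 2).
#' @param bias mean difference B - A, percent.
#' @param sd standard deviation of the differences, percent (>= 0).
#' @param base function of `n` drawing the base (A) values.
#' @param seed integer seed.
#' @return A [paired_set()] with attribute `n_clipped`.
#' @export
generate_paired_differences <- function(n, bias = 0, sd = 1,
                                        base = function(n) runif(n, 1, 30),
                                        seed = 1L) {
  stopifnot(is_count(n), n >= 2, sd >= 0)
  with_seed(seed, {
    a <- base(n)
    b <- a + rnorm(n, mean = bias, sd = sd)
    n_clipped <- sum(a < 0 | a > 100) + sum(b < 0 | b > 100)
    ps <- paired_set(
      subject = sprintf("S%05d", seq_len(n)),
      value_a = clip(a, 0, 100),
      value_b = clip(b, 0, 100),
      labels = c("A", "B")
    )
    attr(ps, "n_clipped") <- n_clipped
    ps
  })
}

# Baseline mean stained fractions (percent) per marker; loosely ordered by
# how abundant each cell population tends to be in inflamed tissue.
DEFAULT_MARKER_BASELINE <- c(
  CD3 = 8, CD4 = 6, CD8 = 5, CD15 = 3, CD20 = 4, CD68 = 5, CD138 = 6
)

#' Simulate a two-group, multi-marker IHC cohort
#'
#' Emulates the measurement structure of a peri-implantitis (PI) versus
#' periodontitis (PD) cohort: `n_per_group` patients per group, each
#' contributing `n_fields` image fields per marker, each field measured by
#' both methods (MC and DC). Field values share a patient-level random
#' effect; group means differ only for the markers named in
#' `marker_effects` (default: macrophage CD68 and plasma-cell CD138
#' elevated in PI).
#'
#' @param n_per_group patients per group (>= 2).
#' @param marker_effects named numeric vector: additive PI-group shift
#'   (percentage points) per marker; markers not named get no effect.
#' @param seed integer seed.
#' @param n_fields fields (pictures) per patient per marker.
#' @param baseline named numeric vector of per-marker baseline means.
#' @param patient_sd SD of the patient random effect, percent.
#' @param field_sd SD of the field-level noise, percent.
#' @param method_offset named numeric vector `c(MC = , DC = )`: additive
#'   method bias applied on top of the latent field value.
#' @param method_sd SD of independent per-measurement method noise.
#' @return A data frame of class `cohort_data` with columns `patient_id`,
#'   `group` ("PI"/"PD"), `marker`, `method`, `field_id`, `value`.
#' @export
generate_cohort <- function(n_per_group = 11L,
                            marker_effects = c(CD68 = 4, CD138 = 4),
                            seed = 1L,
                            n_fields = 4L,
                            baseline = DEFAULT_MARKER_BASELINE,
                            patient_sd = 1.5,
                            field_sd = 1.0,
                            method_offset = c(MC = 0, DC = -0.44),
                            method_sd = 0.5) {
  stopifnot(is_count(n_per_group), n_per_group >= 2, is_count(n_fields))
  markers <- names(DEFAULT_MARKER_BASELINE)
  stopifnot(all(names(marker_effects) %in% markers))
  effects <- stats::setNames(numeric(length(markers)), markers)
  if (length(marker_effects)) effects[names(marker_effects)] <- marker_effects
  with_seed(seed, {
    groups <- rep(c("PI", "PD"), each = n_per_group)
    patients <- sprintf("P%02d", seq_along(groups))
    rows <- vector("list", 0L)
    for (p in seq_along(patients)) {
      for (m in markers) {
        mu <- baseline[[m]] + if (groups[p] == "PI") effects[[m]] else 0
        patient_eff <- rnorm(1, 0, patient_sd)
        latent <- mu + patient_eff + rnorm(n_fields, 0, field_sd)
        for (meth in c("MC", "DC")) {
          val <- latent + method_offset[[meth]] + rnorm(n_fields, 0, method_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = patients[p],
            group = groups[p],
            marker = m,
            method = meth,
            field_id = sprintf("%s_%s_f%d", patients[p], m, seq_len(n_fields)),
            value = clip(val, 0, 100)
          )
        }
      }
    }
    structure(
      do.call(rbind, rows),
      n_per_group = as.integer(n_per_group),
      n_fields = as.integer(n_fields),
      markers = markers,
      class = c("cohort_data", "data.frame")
    )
  })
}
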