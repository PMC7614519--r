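#' Relative RNA level by the delta-Ct method
#'
#' `2^-(ct_target - ct_ref)`: one PCR cycle earlier than the reference
#' doubles the inferred level. Vectorized.
#'
#' @param ct_target Ct of the target RNA.
#' @param ct_ref Ct of the reference (e.g. GAPDH mRNA) in the same sample.
#' @return Dimensionless relative level(s).
#' @examples
#' delta_ct(25, 25)  # 1
#' delta_ct(26, 25)  # 0.5
#' @export
delta_ct <- function(ct_target, ct_ref) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_ref))) {
    abort("Ct values must be finite")
  }
  2^(-(ct_target - ct_ref))
}

default_pooling <- function() {
  list(1:2, 3:4, 5:6, 7:8, 9:10, 11:12)
}

#' Polysome-gradient fraction distribution
#'
#' Sucrose-gradient runs are collected as 12 fractions (top to bottom) and
#' pooled pairwise — fractions 1–2, 3–4, 5–6, 7–8, 9–10, 11–12 — into 6
#' pools before RT-qPCR. Given the 12 per-fraction relative levels
#' (already delta-Ct transformed; see [delta_ct()]), this sums each pool
#' and normalizes to percentages of the total. Pools 1–3 cover the
#' ribosome-free/monosome region of the gradient and pools 4–6 the heavy
#' translating polysomes.
#'
#' @param levels Numeric vector of 12 non-negative per-fraction levels.
#' @param pooling List of index vectors partitioning `1:12` (default the
#'   pairwise pooling above).
#' @param target Optional target label carried into the result.
#' @return A `fraction_profile` tibble: `pool`, `fractions`, `level`,
#'   `percent` (summing to 100), with attribute `target`.
#' @export
fraction_distribution <- function(levels, pooling = default_pooling(),
                                  target = NA_character_) {
  if (length(levels) != 12) abort("expected exactly 12 per-fraction levels")
  if (any(!is.finite(levels)) || any(levels < 0)) {
    abort("levels must be finite and non-negative")
  }
  idx <- sort(unlist(pooling))
  if (!identical(idx, 1:12)) abort("pooling must partition fractions 1..12")
  pooled <- vapply(pooling, function(i) sum(levels[i]), numeric(1))
  total <- sum(pooled)
  if (total <= 0) abort("total signal must be positive")
  out <- tibble(
    pool = seq_along(pooling),
    fractions = vapply(pooling, function(i) paste(range(i), collapse = "-"),
                       character(1)),
    level = pooled,
    percent = 100 * pooled / total
  )
  attr(out, "target") <- target
  class(out) <- c("fraction_profile", class(out))
  out
}

#' @describeIn fraction_distribution Convenience path from raw Cts: the 12
#'   levels are `2^-(ct - ct_ref)` with a per-fraction reference.
#' @param ct Numeric vector of 12 target Cts (fractions 1..12 in order).
#' @param ct_ref Reference Ct(s), length 1 or 12.
#' @export
fraction_distribution_ct <- function(ct, ct_ref, pooling = default_pooling(),
                                     target = NA_character_) {
  fraction_distribution(delta_ct(ct, ct_ref), pooling = pooling,
                        target = target)
}

#' Monosome and polysome shares of a fraction profile
#'
#' @param profile A `fraction_profile` with 6 pools.
#' @return One-row tibble with `monosome_pct` (pools 1–3: ribosome-free
#'   and monosome region) and `polysome_pct` (pools 4–6: translating
#'   polysomes).
#' @export
polysome_share <- function(profile) {
  stopifnot(inherits(profile, "fraction_profile"), nrow(profile) == 6)
  tibble(
    monosome_pct = sum(profile$percent[1:3]),
    polysome_pct = sum(profile$percent[4:6])
  )
}

#' RNA immunoprecipitation fold enrichment
#'
#' Two-stage delta-Ct: the target's reference-normalized level in the IP
#' sample over its reference-normalized level in the IgG control,
#' `2^-(ct_ip - ct_ref_ip) / 2^-(ct_igg - ct_ref_igg)`. Used for HuR RIP
#' and m6A pulldown RT-qPCR readouts.
#'
#' @param ct_ip,ct_igg Target Cts in the IP and IgG samples.
#' @param ct_ref_ip,ct_ref_igg Reference (e.g. GAPDH) Cts in the same two
#'   samples.
#' @return Fold enrichment (dimensionless).
#' @examples
#' ip_enrichment(23, 25, 20, 20)  # 4: target 2 cycles earlier in IP
#' @export
ip_enrichment <- function(ct_ip, ct_igg, ct_ref_ip, ct_ref_igg) {
  delta_ct(ct_ip, ct_ref_ip) / delta_ct(ct_igg, ct_ref_igg)
}
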