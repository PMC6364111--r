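#' Relative correction factor between internal reference and analyte
#'
#' The single-marker method converts the internal reference's
#' response-per-concentration into each analyte's through the relative
#' correction factor
#' \deqn{f_{s/k} = \frac{W_k A_s}{W_s A_k},}
#' where \eqn{A_s, W_s} are the reference's peak area and concentration and
#' \eqn{A_k, W_k} the analyte's. Because it is a ratio of areas measured in
#' the same injection, any factor common to both areas (injection volume,
#' detector gain) cancels.
#'
#' @param ref_conc Reference concentration \eqn{W_s}, ug/mL.
#' @param ref_area Reference peak area \eqn{A_s}.
#' @param k_conc Analyte concentration \eqn{W_k}, ug/mL.
#' @param k_area Analyte peak area \eqn{A_k}.
#' @return Dimensionless RCF \eqn{f_{s/k}}.
#' @examples
#' compute_rcf(ref_conc = 2, ref_area = 100, k_conc = 1, k_area = 25) # 2
#' @export
compute_rcf <- function(ref_conc, ref_area, k_conc, k_area) {
  args <- c(ref_conc = ref_conc, ref_area = ref_area,
            k_conc = k_conc, k_area = k_area)
  bad <- names(args)[args <= 0 | !is.finite(args)]
  if (length(bad))
    stop("nonpositive input(s): ", paste(bad, collapse = ", "))
  (k_conc * ref_area) / (ref_conc * k_area)
}

#' Multipoint relative correction factor
#'
#' Computes one RCF per injection (the standard mixture injected at several
#' volumes at fixed concentrations) and summarises them as their arithmetic
#' mean and relative standard deviation (sample s.d., n - 1).
#'
#' @param injections Either a two-column matrix/data.frame of
#'   `(ref_area, k_area)` pairs, one row per injection, or a list of such
#'   pairs. Alternatively pass precomputed per-injection RCFs via `values`.
#' @param ref_conc,k_conc Standard concentrations, ug/mL (ignored when
#'   `values` is given).
#' @param values Optional precomputed per-injection RCFs.
#' @param analyte_name,internal_reference,wavelength Metadata carried into
#'   the result.
#' @return An object of class `rcf_estimate` with `per_injection_values`,
#'   `mean_rcf` and `rsd_percent`.
#' @export
multipoint_rcf <- function(injections = NULL, ref_conc = NULL,
                           k_conc = NULL, values = NULL,
                           analyte_name = NA_character_,
                           internal_reference = NA_character_,
                           wavelength = NA_real_) {
  if (is.null(values)) {
    m <- as.matrix(as.data.frame(injections))
    if (ncol(m) != 2L) stop("injections must be (ref_area, k_area) pairs")
    values <- vapply(seq_len(nrow(m)), function(i)
      compute_rcf(ref_conc, m[i, 1], k_conc, m[i, 2]), numeric(1))
  }
  if (length(values) < 2L)
    stop("need >= 2 injections: RSD is undefined for a single value")
  if (any(values <= 0)) stop("per-injection RCFs must all be > 0")
  structure(list(analyte_name = analyte_name,
                 internal_reference = internal_reference,
                 wavelength = wavelength,
                 per_injection_values = as.numeric(values),
                 mean_rcf = mean(values),
                 rsd_percent = rsd(values)),
            class = "rcf_estimate")
}

#' @export
print.rcf_estimate <- function(x, ...) {
  cat(sprintf("<RCF> %s vs %s @ %s nm: mean %.2f, RSD %.2f%% (n = %d)\n",
              x$analyte_name, x$internal_reference, format(x$wavelength),
              x$mean_rcf, x$rsd_percent, length(x$per_injection_values)))
  invisible(x)
}

#' Relative retention time
#'
#' Ratio of an analyte's retention time to the internal reference's,
#' \eqn{Rt_R = t_{Rk} / t_{Rs}}. Invariant under a common rescaling of the
#' time axis, which is why it localizes peaks more reproducibly across
#' instruments and flow rates than the absolute retention-time difference.
#'
#' @param t_rk Analyte retention time, minutes (> 0).
#' @param t_rs Reference retention time, minutes (> 0).
#' @return Dimensionless ratio.
#' @export
relative_retention <- function(t_rk, t_rs) {
  if (any(t_rk <= 0) || any(t_rs <= 0))
    stop("retention times must be > 0")
  t_rk / t_rs
}

#' Locate analyte peaks by relative retention time
#'
#' Given the detected peaks of a sample run and the identified internal
#' reference peak, assigns each target analyte to the detected peak whose
#' observed relative retention is nearest its expected value, provided the
#' relative deviation is within tolerance. Each peak is used at most once
#' (greedy best-first assignment); targets with no acceptable peak are
#' reported absent (`NA` row index), which is what a negative control
#' lacking an analyte should produce.
#'
#' Ties (two candidate peaks equidistant in relative retention) break
#' deterministically to the earlier-eluting peak.
#'
#' @param sample_peaks A `peak_table` from [detect_peaks()].
#' @param reference_peak The reference analyte's row of a peak table (error
#'   if missing/NULL: localization is impossible without the anchor).
#' @param targets data.frame with columns `analyte` and `expected_rtr`, and
#'   optionally `tolerance` (fractional; default 0.05).
#' @param tolerance Default fractional tolerance for targets without one.
#' @return data.frame with one row per target: `analyte`, `expected_rtr`,
#'   `observed_rtr`, `apex_time`, `area`, `height`, `peak_row` (`NA` when
#'   absent).
#' @export
locate_peaks_by_rtr <- function(sample_peaks, reference_peak, targets,
                                tolerance = 0.05) {
  if (is.null(reference_peak) || !length(reference_peak$apex_time) ||
      is.na(reference_peak$apex_time))
    stop("reference peak missing: cannot anchor relative retention")
  if (!nrow(targets)) stop("targets must be nonempty")
  if (is.null(targets$tolerance)) targets$tolerance <- tolerance
  t_rs <- reference_peak$apex_time
  obs_rtr <- if (nrow(sample_peaks))
    relative_retention(sample_peaks$apex_time, t_rs) else numeric(0)

  # all (target, peak) pairs within tolerance, best matches first;
  # tie-break on earlier apex time
  pairs <- expand.grid(ti = seq_len(nrow(targets)),
                       pi = seq_len(max(nrow(sample_peaks), 0L)))
  if (nrow(sample_peaks) && nrow(pairs)) {
    pairs$dev <- abs(obs_rtr[pairs$pi] - targets$expected_rtr[pairs$ti]) /
      targets$expected_rtr[pairs$ti]
    pairs <- pairs[pairs$dev <= targets$tolerance[pairs$ti], , drop = FALSE]
    pairs <- pairs[order(pairs$dev, sample_peaks$apex_time[pairs$pi]), ,
                   drop = FALSE]
  } else pairs <- pairs[0, ]

  assigned_peak <- rep(NA_integer_, nrow(targets))
  used <- logical(nrow(sample_peaks))
  for (r in seq_len(nrow(pairs))) {
    ti <- pairs$ti[r]; pi <- pairs$pi[r]
    if (is.na(assigned_peak[ti]) && !used[pi]) {
      assigned_peak[ti] <- pi
      used[pi] <- TRUE
    }
  }
  data.frame(analyte = targets$analyte,
             expected_rtr = targets$expected_rtr,
             observed_rtr = ifelse(is.na(assigned_peak), NA_real_,
                                   obs_rtr[assigned_peak]),
             apex_time = ifelse(is.na(assigned_peak), NA_real_,
                                sample_peaks$apex_time[assigned_peak]),
             area = ifelse(is.na(assigned_peak), NA_real_,
                           sample_peaks$area[assigned_peak]),
             height = ifelse(is.na(assigned_peak), NA_real_,
                             sample_peaks$height[assigned_peak]),
             peak_row = assigned_peak)
}

#' Single-marker (QAMS) content of an analyte
#'
#' Rearranges the RCF definition with sample-run quantities: the analyte
#' concentration implied by the reference's measured concentration, the two
#' sample-run areas, and the pre-established RCF is
#' `rcf x ref_conc_in_sample x k_area / ref_area`.
#'
#' @param rcf Pre-established relative correction factor (> 0).
#' @param k_area Analyte peak area in the sample run.
#' @param ref_area Reference peak area in the same run.
#' @param ref_conc_in_sample Reference concentration in the sample, ug/mL
#'   (obtained by external standard on the reference's own curve).
#' @return Analyte concentration, ug/mL.
#' @export
qams_content <- function(rcf, k_area, ref_area, ref_conc_in_sample) {
  args <- c(rcf = rcf, k_area = k_area, ref_area = ref_area,
            ref_conc_in_sample = ref_conc_in_sample)
  bad <- names(args)[args <= 0 | !is.finite(args)]
  if (length(bad))
    stop("nonpositive input(s): ", paste(bad, collapse = ", "))
  rcf * ref_conc_in_sample * k_area / ref_area
}

#' Mass fraction of an analyte in the weighed sample
#'
#' Converts an extract concentration to a percentage of the sample mass:
#' `(conc x final_volume) / (sample_mass x 1e6) x 100`.
#'
#' @param conc Analyte concentration in the extract, ug/mL.
#' @param final_volume Extract final volume, mL.
#' @param sample_mass Weighed sample mass, g.
#' @return Mass fraction in percent.
#' @export
mass_fraction <- function(conc, final_volume, sample_mass) {
  if (any(conc <= 0) || final_volume <= 0 || sample_mass <= 0)
    stop("all inputs must be > 0")
  (conc * final_volume) / (sample_mass * 1e6) * 100
}

#' Signed relative error between external-standard and QAMS contents
#'
#' `RE = (ES - QAMS) / ES x 100`. Undefined (NA) when the external-standard
#' value is zero or missing -- the convention used for the internal
#' reference, which has no independent single-marker value.
#'
#' @param es External-standard content (mass percent).
#' @param qams QAMS content (mass percent).
#' @return Signed percentage (NA where undefined).
#' @export
relative_error <- function(es, qams) {
  out <- ifelse(is.na(es) | es == 0, NA_real_, (es - qams) / es * 100)
  if (any(!is.na(es) & es < 0)) stop("es must be > 0 where defined")
  out
}
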