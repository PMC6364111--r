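#' Relative standard deviation
#'
#' `100 x sample s.d. (n - 1) / mean`. Scale-invariant: multiplying every
#' value by a positive constant leaves the RSD unchanged.
#'
#' @param values Numeric vector, length >= 2, mean != 0.
#' @return RSD in percent.
#' @examples
#' rsd(c(3.80, 3.85, 3.81, 3.73, 3.82)) # 1.17 at 2 d.p.
#' @export
rsd <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero: RSD undefined")
  stats::sd(values) / m * 100
}

#' Spike recovery rate
#'
#' `(found - original) / added x 100`: the percentage of a known added
#' amount that the method finds on top of the un-spiked content.
#'
#' @param original Amount present before spiking, ug.
#' @param added Spiked amount, ug (> 0).
#' @param found Amount measured after spiking, ug.
#' @return Recovery in percent.
#' @export
recovery_rate <- function(original, added, found) {
  if (any(added <= 0)) stop("added must be > 0")
  (found - original) / added * 100
}

#' Replicate-injection precision summary
#'
#' RSD of replicate peak areas (or contents) per analyte, with a pass flag
#' at a configurable threshold. Analytes whose series is missing are listed
#' as untested rather than failed.
#'
#' @param series Named list: one numeric vector of replicate values per
#'   analyte (`NULL` entries allowed).
#' @param threshold Pass threshold, percent RSD.
#' @param label Label for the `test` column (precision, stability,
#'   repeatability...).
#' @return data.frame with `test`, `analyte`, `n`, `rsd_percent`,
#'   `threshold`, `pass` (`NA` for untested).
#' @export
run_precision_suite <- function(series, threshold = 2.0,
                                label = "precision") {
  if (is.null(names(series)))
    names(series) <- paste0("series", seq_along(series))
  rows <- lapply(names(series), function(nm) {
    v <- series[[nm]]
    if (is.null(v) || length(v) < 2L)
      return(data.frame(test = label, analyte = nm, n = length(v),
                        rsd_percent = NA_real_, threshold = threshold,
                        pass = NA))
    r <- rsd(v)
    data.frame(test = label, analyte = nm, n = length(v),
               rsd_percent = r, threshold = threshold,
               pass = r <= threshold)
  })
  do.call(rbind, rows)
}

#' Robustness of relative correction factors across conditions
#'
#' Given RCF measurements over a grid of chromatographic conditions
#' (instrument, column, flow rate, temperature...), computes the RSD of
#' each analyte's RCF along each axis and the overall per-analyte maximum.
#' An axis with fewer than two conditions is skipped with a warning.
#'
#' @param grid data.frame with columns `axis` (condition family),
#'   `condition`, `analyte`, `rcf`.
#' @param threshold Pass threshold on the maximum RSD, percent.
#' @return list with `by_axis` (data.frame `axis,analyte,n,rsd_percent`),
#'   `summary` (data.frame `analyte,max_rsd_percent,pass`), and
#'   `max_rsd_percent` overall.
#' @export
rcf_robustness <- function(grid, threshold = 2.27) {
  stopifnot(all(c("axis", "condition", "analyte", "rcf") %in% names(grid)))
  by_axis <- NULL
  for (ax in unique(grid$axis)) {
    g <- grid[grid$axis == ax, ]
    if (length(unique(g$condition)) < 2L) {
      warning(sprintf("axis '%s' has a single condition: skipped", ax))
      next
    }
    for (an in unique(g$analyte)) {
      v <- g$rcf[g$analyte == an]
      by_axis <- rbind(by_axis,
                       data.frame(axis = ax, analyte = an, n = length(v),
                                  rsd_percent = rsd(v)))
    }
  }
  if (is.null(by_axis)) stop("no axis with >= 2 conditions")
  summary <- do.call(rbind, lapply(unique(by_axis$analyte), function(an) {
    mx <- max(by_axis$rsd_percent[by_axis$analyte == an])
    data.frame(analyte = an, max_rsd_percent = mx, pass = mx <= threshold)
  }))
  list(by_axis = by_axis, summary = summary,
       max_rsd_percent = max(summary$max_rsd_percent))
}

#' Compare peak-localization strategies across conditions
#'
#' For every analyte, computes the RSD across conditions of (a) the
#' absolute retention-time difference `t_Rk - t_Rs` and (b) the relative
#' retention `t_Rk / t_Rs`, and declares the more reproducible method the
#' winner. Under clock-scale drift (flow-rate or instrument changes that
#' stretch the whole time axis) the ratio is invariant and wins; under a
#' pure additive shift the difference wins.
#'
#' @param rt_grid data.frame with columns `condition`, `analyte`,
#'   `retention_time` (minutes); must include the reference analyte in
#'   every condition.
#' @param reference Name of the internal reference analyte.
#' @return data.frame per analyte (reference excluded): `analyte`,
#'   `rsd_difference_percent`, `rsd_ratio_percent`, `winner`.
#' @export
compare_localization_methods <- function(rt_grid, reference) {
  stopifnot(all(c("condition", "analyte", "retention_time") %in%
                  names(rt_grid)))
  conds <- unique(rt_grid$condition)
  ref_rt <- vapply(conds, function(cn) {
    v <- rt_grid$retention_time[rt_grid$condition == cn &
                                  rt_grid$analyte == reference]
    if (length(v) != 1L)
      stop(sprintf("reference '%s' missing in condition '%s'",
                   reference, cn))
    v
  }, numeric(1))
  if (length(conds) < 2L) stop("need >= 2 conditions")
  analytes <- setdiff(unique(rt_grid$analyte), reference)
  out <- do.call(rbind, lapply(analytes, function(an) {
    rt_k <- vapply(conds, function(cn) {
      v <- rt_grid$retention_time[rt_grid$condition == cn &
                                    rt_grid$analyte == an]
      if (length(v) != 1L) NA_real_ else v
    }, numeric(1))
    keep <- !is.na(rt_k)
    d <- rt_k[keep] - ref_rt[keep]
    q <- rt_k[keep] / ref_rt[keep]
    rd <- abs(rsd(d))    # difference can be negative-mean; compare spreads
    rq <- abs(rsd(q))
    data.frame(analyte = an, rsd_difference_percent = rd,
               rsd_ratio_percent = rq,
               winner = if (rq < rd) "relative_retention"
                        else if (rd < rq) "retention_difference"
                        else "tie")
  }))
  rownames(out) <- NULL
  out
}

#' Write a validation report
#'
#' One row per (test, analyte) with the statistic, threshold and pass flag,
#' written as CSV and mirrored as JSON.
#'
#' @param report data.frame as produced by [run_precision_suite()] (rows
#'   from several tests may be stacked).
#' @param path Output CSV path; `<path>.json` is written alongside.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  jsonlite::write_json(report, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
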