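# Surgical-efficacy arithmetic: per-band insertion loss of a reconstruction
# stack applied to a pre-operative tinnitus spectrum, amplitude reductions,
# the three-technique comparison, and the resolution decision rule.

#' Apply a stack's insertion loss to a pre-operative spectrum
#'
#' Band-wise subtraction `post = pre - TL`, floored at 0 dB SPL
#' (audibility floor rather than physical silence). The stack's
#' transmission loss is evaluated on the pre-spectrum's band centers.
#'
#' @param pre_spectrum A [band_spectrum] of pre-operative levels (dB SPL).
#' @param stack A [reconstruction_stack], or `NULL` for no intervention.
#' @param medium An [acoustic_medium].
#' @return A [band_spectrum] of post-operative levels.
#' @export
apply_insertion_loss <- function(pre_spectrum, stack,
                                 medium = acoustic_medium()) {
  stopifnot(inherits(pre_spectrum, "band_spectrum"))
  if (is.null(stack)) return(pre_spectrum)
  tl <- composite_stack_tl(stack, pre_spectrum$centers, medium)
  post <- pmax(pre_spectrum$values - tl$tl, 0)
  band_spectrum(post, pre_spectrum$band_set, centers = pre_spectrum$centers)
}

#' Amplitude reduction in dB
#'
#' @param pre_peak,post_peak Peak levels in dB (finite).
#' @return `pre_peak - post_peak`.
#' @examples
#' reduction(64.0, 47.3) # 16.7 dB
#' @export
reduction <- function(pre_peak, post_peak) {
  if (!all(is.finite(c(pre_peak, post_peak)))) {
    stop("peaks must be finite", call. = FALSE)
  }
  pre_peak - post_peak
}

#' Resolution decision rule
#'
#' The tinnitus is deemed resolved when the achieved reduction (the total
#' transmission loss of the reconstruction) reaches the measured loudness
#' of the tinnitus above the hearing threshold; the boundary case counts
#' as resolved.
#'
#' @param reduction Achieved reduction in dB.
#' @param loudness_above_threshold Loudness above threshold in dB, default
#'   17.7 (cohort mean).
#' @return Logical.
#' @examples
#' resolution_decision(30.4) # TRUE
#' resolution_decision(4.2)  # FALSE
#' @export
resolution_decision <- function(reduction, loudness_above_threshold = 17.7) {
  if (loudness_above_threshold < 0) {
    stop("loudness_above_threshold must be non-negative", call. = FALSE)
  }
  reduction >= loudness_above_threshold
}

#' One reconstruction-technique case
#'
#' A technique is described either by its simulated post-reconstruction
#' peaks (reproducing coupled-simulation outputs) or by a material stack
#' from which the insertion loss is predicted.
#'
#' @param label Technique label, e.g. `"TF-AC"`, `"SGS"`, `"SGS-BW"`.
#' @param pre_vibro_peak,pre_hydro_peak Pre-reconstruction peak levels of
#'   the vibroacoustic and hydroacoustic sources (dB).
#' @param post_vibro_peak,post_hydro_peak Post-reconstruction peaks (dB);
#'   may be omitted when `stack` is given.
#' @param stack Optional [reconstruction_stack] for predictive mode.
#' @param loudness_above_threshold Decision threshold in dB, default 17.7.
#' @return An object of class `efficacy_case`.
#' @export
efficacy_case <- function(label, pre_vibro_peak, pre_hydro_peak,
                          post_vibro_peak = NA_real_,
                          post_hydro_peak = NA_real_, stack = NULL,
                          loudness_above_threshold = 17.7) {
  if (!all(is.finite(c(pre_vibro_peak, pre_hydro_peak)))) {
    stop("pre peaks must be finite", call. = FALSE)
  }
  structure(
    list(label = label, pre_vibro_peak = pre_vibro_peak,
         pre_hydro_peak = pre_hydro_peak,
         post_vibro_peak = post_vibro_peak,
         post_hydro_peak = post_hydro_peak, stack = stack,
         loudness_above_threshold = loudness_above_threshold),
    class = "efficacy_case"
  )
}

#' Compare reconstruction techniques
#'
#' Computes per-case vibroacoustic and hydroacoustic reductions
#' (`pre - post`) and the resolution decision. Cases configured with a
#' stack but no post peaks get their post peaks from the stack's band-mean
#' transmission loss applied to the pre peaks.
#'
#' @param cases List of [efficacy_case] objects.
#' @param medium An [acoustic_medium].
#' @return An object of class `efficacy_report`: a data.frame with columns
#'   `label`, `pre_vibro`, `pre_hydro`, `post_vibro`, `post_hydro`,
#'   `reduction_vibro`, `reduction_hydro`, `resolved`.
#' @examples
#' rep <- technique_comparison(list(
#'   efficacy_case("TF-AC", 72.8, 70.4, 68.6, 65.9),
#'   efficacy_case("SGS-BW", 72.8, 70.4, 42.4, 39.2)))
#' rep$reduction_vibro # 4.2, 30.4
#' @export
technique_comparison <- function(cases, medium = acoustic_medium()) {
  if (inherits(cases, "efficacy_case")) cases <- list(cases)
  rows <- lapply(cases, function(cs) {
    stopifnot(inherits(cs, "efficacy_case"))
    post_v <- cs$post_vibro_peak
    post_h <- cs$post_hydro_peak
    if ((is.na(post_v) || is.na(post_h))) {
      if (is.null(cs$stack)) {
        stop(sprintf("case '%s' has neither post peaks nor a stack",
                     cs$label), call. = FALSE)
      }
      tl <- composite_stack_tl(cs$stack, band_centers("tl13"), medium)
      il <- mean(tl$tl)
      if (is.na(post_v)) post_v <- max(cs$pre_vibro_peak - il, 0)
      if (is.na(post_h)) post_h <- max(cs$pre_hydro_peak - il, 0)
    }
    red_v <- reduction(cs$pre_vibro_peak, post_v)
    red_h <- reduction(cs$pre_hydro_peak, post_h)
    data.frame(
      label = cs$label, pre_vibro = cs$pre_vibro_peak,
      pre_hydro = cs$pre_hydro_peak, post_vibro = post_v,
      post_hydro = post_h, reduction_vibro = red_v,
      reduction_hydro = red_h,
      resolved = resolution_decision(min(red_v, red_h),
                                     cs$loudness_above_threshold),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("efficacy_report", "data.frame")
  out
}

#' @export
print.efficacy_report <- function(x, ...) {
  cat("Reconstruction-technique efficacy report\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read efficacy cases from YAML
#'
#' Reads a YAML list of cases (the package ships the simulated
#' three-technique comparison at
#' `system.file("extdata", "techniques.yaml", package = "ptinsulate")`).
#'
#' @param path YAML path.
#' @return List of [efficacy_case] objects.
#' @export
read_efficacy_cases <- function(path = system.file("extdata",
                                                   "techniques.yaml",
                                                   package = "ptinsulate")) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(cs) {
    efficacy_case(
      label = cs$label,
      pre_vibro_peak = cs$pre_vibro_peak,
      pre_hydro_peak = cs$pre_hydro_peak,
      post_vibro_peak = cs$post_vibro_peak %||% NA_real_,
      post_hydro_peak = cs$post_hydro_peak %||% NA_real_,
      loudness_above_threshold = cs$loudness_above_threshold %||% 17.7
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
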