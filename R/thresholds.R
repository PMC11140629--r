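#' Analysis thresholds for outcome and exposure derivation
#'
#' Bundles every clinical cut-point the deterministic classifiers use, with
#' defaults matching the standard conventions for paediatric Crohn's disease:
#' early anti-TNF is therapy started within 90 days of diagnosis; normal-CRP
#' remission requires CRP < 0.5 mg/dl; normal-FCP remission requires faecal
#' calprotectin < 250 ug/g; a three-month FCP response is a >= 50% drop (or
#' FCP < 250); small/moderate clinical response are wPCDAI decreases of
#' > 17.5 / > 37.5 points; growth delay is a height-for-age Z-score strictly
#' below -1.5; SES-CD < 3 is mucosal healing and >= 10 moderate-to-severe;
#' the MINI-index mucosal-healing proxy boundary is < 3.
#'
#' The four wPCDAI activity groups use cut points 12.5 / 40 / 57.5
#' (remission < 12.5; mild 12.5-40; moderate > 40 to 57.5; severe > 57.5),
#' taken from the published wPCDAI validation work; they are exposed here
#' because the exact banding convention varies between reports.
#'
#' @param early_window_days days after diagnosis defining "early" therapy.
#' @param ncr_crp_max CRP upper bound (exclusive), mg/dl.
#' @param nfr_fcp_max faecal calprotectin upper bound (exclusive), ug/g.
#' @param fcp_response_fraction proportional FCP drop counting as response
#'   (inclusive).
#' @param small_response_drop,moderate_response_drop wPCDAI point decreases
#'   (exclusive) defining small / moderate response.
#' @param growth_delay_z HFA Z-score below which (strictly) growth delay holds.
#' @param sescd_mh_max SES-CD below which (strictly) mucosal healing holds.
#' @param sescd_modsev_min SES-CD at or above which disease is
#'   moderate-to-severe.
#' @param mini_mh_max MINI-index below which (strictly) the mucosal-healing
#'   proxy holds.
#' @param mini_mild_max MINI-index upper bound (inclusive) of the "mild"
#'   band. No published boundary exists; this default is unvalidated and only
#'   the mucosal-healing boundary enters headline outcomes.
#' @param wpcdai_cuts three strictly ascending wPCDAI cut points.
#' @param steroid_free_from_day start (exclusive) of the steroid-free window
#'   for sustained outcomes; defaults to the day after the early-therapy
#'   window so induction steroids within the first three months do not
#'   violate steroid-freedom.
#' @return a list of class `analysis_thresholds`.
#' @examples
#' th <- analysis_thresholds()
#' th$wpcdai_cuts
#' @export
analysis_thresholds <- function(early_window_days = 90,
                                ncr_crp_max = 0.5,
                                nfr_fcp_max = 250,
                                fcp_response_fraction = 0.50,
                                small_response_drop = 17.5,
                                moderate_response_drop = 37.5,
                                growth_delay_z = -1.5,
                                sescd_mh_max = 3,
                                sescd_modsev_min = 10,
                                mini_mh_max = 3,
                                mini_mild_max = 8,
                                wpcdai_cuts = c(12.5, 40, 57.5),
                                steroid_free_from_day = early_window_days + 1) {
  th <- list(
    early_window_days = early_window_days,
    ncr_crp_max = ncr_crp_max,
    nfr_fcp_max = nfr_fcp_max,
    fcp_response_fraction = fcp_response_fraction,
    small_response_drop = small_response_drop,
    moderate_response_drop = moderate_response_drop,
    growth_delay_z = growth_delay_z,
    sescd_mh_max = sescd_mh_max,
    sescd_modsev_min = sescd_modsev_min,
    mini_mh_max = mini_mh_max,
    mini_mild_max = mini_mild_max,
    wpcdai_cuts = wpcdai_cuts,
    steroid_free_from_day = steroid_free_from_day
  )
  nums <- unlist(th)
  if (any(!is.finite(nums))) stop("all thresholds must be finite", call. = FALSE)
  if (length(wpcdai_cuts) != 3L || is.unsorted(wpcdai_cuts, strictly = TRUE)) {
    stop("'wpcdai_cuts' must be three strictly ascending values", call. = FALSE)
  }
  if (sescd_mh_max > sescd_modsev_min) {
    stop("'sescd_mh_max' must not exceed 'sescd_modsev_min'", call. = FALSE)
  }
  structure(th, class = "analysis_thresholds")
}
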