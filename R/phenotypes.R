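#' Cortisol area under the curve
#'
#' Trapezoidal integration of the four salivary cortisol concentrations over
#' clock time (default 07:00, 10:00, 13:00, 16:00; span 9 h). Units:
#' concentration x hours. Linear in the concentrations; missing points are an
#' error (no imputation).
#'
#' @param conc numeric vector of 4 non-negative concentrations.
#' @param times sampling clock times in hours (default c(7, 10, 13, 16)).
#' @return AUC.
#' @export
cortisol_auc <- function(conc, times = c(7, 10, 13, 16)) {
  if (length(conc) != length(times) || anyNA(conc))
    stop("need one non-missing concentration per time point")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  dt <- diff(times)
  sum(dt * (utils::head(conc, -1) + utils::tail(conc, -1)) / 2)
}

#' Average daily gain and feed conversion ratio
#'
#' ADG = (final - initial weight) / days on trial; FCR = DFI / ADG. FCR is
#' undefined (NA, with a warning) when ADG <= 0.
#'
#' @param weights weekly body weights (kg), first = trial start, last = end.
#' @param days total days on trial.
#' @param dfi daily feed intake (kg/day), optional.
#' @return list: adg, fcr (NA if no dfi or ADG <= 0).
#' @export
growth_traits <- function(weights, days, dfi = NULL) {
  if (any(weights <= 0)) stop("weights must be positive")
  adg <- (weights[length(weights)] - weights[1]) / days
  fcr <- NA_real_
  if (!is.null(dfi)) {
    if (adg <= 0) warning("ADG <= 0; FCR undefined")
    else fcr <- dfi / adg
  }
  list(adg = adg, fcr = fcr)
}

#' Apportion pen feed totals to individual animals
#'
#' Individual daily feed intake is estimated by splitting each pen's total
#' proportionally to a predicted intake a * w^0.75 + b * ADG (metabolic-weight
#' maintenance plus growth), so individual DFIs sum exactly to the pen total.
#'
#' @param pen_totals named numeric: total feed (kg/day) per pen.
#' @param pen factor/character: pen of each animal.
#' @param weights mean body weight (kg) of each animal over the trial.
#' @param gains ADG (kg/day) of each animal.
#' @param a,b allocation coefficients (defaults 0.1 and 1.5; only their ratio
#'   matters within a pen).
#' @return numeric vector of per-animal DFI; NA for animals in pens with a
#'   missing total.
#' @export
estimate_individual_dfi <- function(pen_totals, pen, weights, gains,
                                    a = 0.1, b = 1.5) {
  pen <- as.character(pen)
  stopifnot(length(pen) == length(weights), length(pen) == length(gains))
  pred <- a * weights^0.75 + b * pmax(gains, 0)
  dfi <- rep(NA_real_, length(pen))
  for (pn in unique(pen)) {
    idx <- which(pen == pn)
    tot <- pen_totals[[pn]]
    if (is.null(tot) || is.na(tot)) next
    w <- pred[idx]
    dfi[idx] <- if (sum(w) > 0) tot * w / sum(w) else tot / length(idx)
  }
  dfi
}

#' Total lesion score
#'
#' Sum of new-lesion counts over the six body zones (front/middle/rear x
#' left/right) for one animal and week.
#'
#' @param zone_counts numeric vector (length 6) or matrix weeks x 6 zones of
#'   non-negative integer counts.
#' @return total per week (vector) or single total for a vector input.
#' @export
lesion_total <- function(zone_counts) {
  if (any(zone_counts < 0)) stop("lesion counts must be non-negative")
  if (any(abs(zone_counts - round(zone_counts)) > 1e-8))
    stop("lesion counts must be integers")
  if (is.matrix(zone_counts)) rowSums(zone_counts) else sum(zone_counts)
}

#' Group contrasts for the phenotype layer
#'
#' For every phenotype column, reports group means with SE and the
#' control - stress difference with SE and Wald p from the shared
#' [mixed_contrast()] (treatment fixed, litter random).
#'
#' @param phenotypes data.frame with `animal_id` plus numeric trait columns.
#' @param metadata data.frame with animal_id, treatment, litter (one row per
#'   animal; a sample-level metadata table is collapsed automatically).
#' @param traits trait columns to contrast (default: all numeric columns).
#' @return data.frame: trait, mean/SE per group, difference (control -
#'   stress), SE, p.
#' @export
phenotype_contrasts <- function(phenotypes, metadata, traits = NULL) {
  md <- unique(as.data.frame(metadata)[, c("animal_id", "treatment", "litter")])
  if (anyDuplicated(md$animal_id)) stop("inconsistent animal-level metadata")
  i <- match(phenotypes$animal_id, md$animal_id)
  if (anyNA(i)) stop("animal(s) absent from metadata: ",
                     paste(phenotypes$animal_id[is.na(i)], collapse = ", "))
  treatment <- base::factor(md$treatment[i], levels = c("stress", "control"))
  litter <- base::factor(md$litter[i])
  if (is.null(traits))
    traits <- names(phenotypes)[vapply(phenotypes, is.numeric, logical(1))]
  rows <- lapply(traits, function(tr) {
    y <- phenotypes[[tr]]
    ok <- !is.na(y)
    mc <- mixed_contrast(y[ok], treatment[ok], litter[ok],
                         contrast = c("control", "stress"))
    data.frame(trait = tr,
               control_mean = unname(mc$group_means["control"]),
               control_se = unname(mc$group_se["control"]),
               stress_mean = unname(mc$group_means["stress"]),
               stress_se = unname(mc$group_se["stress"]),
               difference = mc$estimate, difference_se = mc$se, p = mc$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Animal-level phenotype summary from raw records
#'
#' Collapses the generator's (or a real study's) raw phenotype records into
#' one row per animal: ADG, estimated DFI, FCR, mean cortisol AUC over the
#' trial sampling days, and mean weekly total lesion score.
#'
#' @param records list as produced by [generate_phenotypes()]: `weights`
#'   (animals x weeks kg), `pen_totals`, `pen`, `cortisol` (array animals x
#'   4 times x days), `lesions` (array animals x weeks x 6 zones), `days`.
#' @param trial_days_only use only the on-trial cortisol days (drop day 1 =
#'   habituation baseline) when averaging AUC (default TRUE).
#' @return data.frame, one row per animal: animal_id, adg, dfi, fcr,
#'   cortisol_auc, lesion_score.
#' @export
summarize_phenotypes <- function(records, trial_days_only = TRUE) {
  w <- records$weights
  n <- nrow(w)
  adg <- (w[, ncol(w)] - w[, 1]) / records$days
  mean_w <- rowMeans(w)
  dfi <- estimate_individual_dfi(records$pen_totals, records$pen, mean_w, adg)
  fcr <- ifelse(adg > 0, dfi / adg, NA_real_)
  day_idx <- seq_len(dim(records$cortisol)[3])
  if (trial_days_only && length(day_idx) > 1) day_idx <- day_idx[-1]
  auc <- vapply(seq_len(n), function(i)
    mean(vapply(day_idx, function(d) cortisol_auc(records$cortisol[i, , d]),
                numeric(1))), numeric(1))
  lesions <- vapply(seq_len(n), function(i)
    mean(lesion_total(records$lesions[i, , ])), numeric(1))
  data.frame(animal_id = rownames(w), adg = unname(adg), dfi = dfi,
             fcr = unname(fcr), cortisol_auc = auc, lesion_score = lesions,
             row.names = NULL)
}
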