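#' @include AllClasses.R disorder.R
NULL

.TIERS <- c("HighlyDisordered", "HighlyOrdered", "ModeratelyDisordered",
            "ModeratelyOrderedOrMildlyFlexible")
.ADS_TIERS <- c("HighlyOrdered", "ModeratelyDisordered", "HighlyDisordered")

#' Classification thresholds for disorder tiers
#'
#' @param ppdr_low,ppdr_high PPDR cut points in percent (defaults 10, 30).
#' @param ads_low,ads_high ADS cut points (defaults 0.15, 0.5).
#' @return a named list, validated so low < high on both axes.
#' @export
classificationThresholds <- function(ppdr_low = 10, ppdr_high = 30,
                                     ads_low = 0.15, ads_high = 0.5) {
  stopifnot(ppdr_low < ppdr_high, ads_low < ads_high)
  list(ppdr_low = ppdr_low, ppdr_high = ppdr_high,
       ads_low = ads_low, ads_high = ads_high)
}

#' Average disorder score (ADS)
#'
#' Arithmetic mean of a protein's per-residue disorder scores.
#'
#' @param profile numeric vector of per-residue scores in [0, 1].
#' @return scalar in [0, 1].
#' @export
ads <- function(profile) {
  if (length(profile) == 0L) stop("empty profile")
  mean(profile)
}

#' Percentage of predicted disordered residues (PPDR)
#'
#' Percent of residues whose disorder score is strictly above 0.5.
#'
#' @inheritParams ads
#' @return percent in [0, 100].
#' @export
ppdr <- function(profile) {
  if (length(profile) == 0L) stop("empty profile")
  100 * mean(profile > 0.5)
}

#' Two-axis (ADS x PPDR) disorder tier
#'
#' Assigns one of four tiers, evaluated in order:
#' \enumerate{
#'   \item \code{HighlyDisordered}: PPDR >= ppdr_high OR ADS >= ads_high
#'     (with \code{rule = "and"}, both are required);
#'   \item \code{HighlyOrdered}: PPDR < ppdr_low AND ADS < ads_low;
#'   \item \code{ModeratelyDisordered}: ppdr_low <= PPDR < ppdr_high AND
#'     ads_low <= ADS < ads_high;
#'   \item \code{ModeratelyOrderedOrMildlyFlexible} otherwise (discordant
#'     low/mid combinations fall here).
#' }
#'
#' @param ads_value ADS in [0, 1] (vectorised).
#' @param ppdr_value PPDR in [0, 100] (vectorised).
#' @param thresholds see [classificationThresholds()].
#' @param rule combination rule for the HighlyDisordered tier: \code{"or"}
#'   (default) or \code{"and"}.
#' @return character vector of tier labels.
#' @examples
#' classifyTwoAxis(0.6, 45)
#' classifyTwoAxis(0.30, 5)   # discordant -> residual tier
#' @export
classifyTwoAxis <- function(ads_value, ppdr_value,
                            thresholds = classificationThresholds(),
                            rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot(length(ads_value) == length(ppdr_value))
  if (any(ads_value < 0 | ads_value > 1, na.rm = FALSE) ||
      any(ppdr_value < 0 | ppdr_value > 100))
    stop("ads must lie in [0, 1] and ppdr in [0, 100]")
  th <- thresholds
  hd <- if (rule == "or")
    ppdr_value >= th$ppdr_high | ads_value >= th$ads_high
  else
    ppdr_value >= th$ppdr_high & ads_value >= th$ads_high
  ho <- ppdr_value < th$ppdr_low & ads_value < th$ads_low
  md <- ppdr_value >= th$ppdr_low & ppdr_value < th$ppdr_high &
    ads_value >= th$ads_low & ads_value < th$ads_high
  out <- rep(.TIERS[4], length(ads_value))
  out[md] <- .TIERS[3]
  out[ho & !md] <- .TIERS[2]
  out[hd] <- .TIERS[1]
  out
}

#' ADS-only disorder tier
#'
#' Three-way split on ADS alone: HighlyOrdered (ADS < 0.15),
#' ModeratelyDisordered (0.15 <= ADS < 0.5), HighlyDisordered (ADS >= 0.5).
#'
#' @inheritParams classifyTwoAxis
#' @return character vector of tier labels.
#' @export
classifyAdsOnly <- function(ads_value,
                            thresholds = classificationThresholds()) {
  if (any(ads_value < 0 | ads_value > 1)) stop("ads must lie in [0, 1]")
  out <- rep(.ADS_TIERS[2], length(ads_value))
  out[ads_value < thresholds$ads_low] <- .ADS_TIERS[1]
  out[ads_value >= thresholds$ads_high] <- .ADS_TIERS[3]
  out
}

#' Per-protein disorder summary for a proteome
#'
#' @param proteome a [Proteome-class].
#' @param profiles per-residue profiles as returned by [disorderProfiles()]
#'   (must cover every protein).
#' @param thresholds see [classificationThresholds()].
#' @param rule passed to [classifyTwoAxis()].
#' @return \code{DataFrame} with columns id, ads, ppdr, tier, ads_only_tier.
#' @export
disorderSummary <- function(proteome, profiles,
                            thresholds = classificationThresholds(),
                            rule = c("or", "and")) {
  rule <- match.arg(rule)
  ids <- proteinIds(proteome)
  profiles <- as.list(profiles)
  missing <- setdiff(ids, names(profiles))
  if (length(missing))
    stop("missing profile(s) for: ", paste(head(missing, 5), collapse = ", "))
  a <- vapply(profiles[ids], ads, numeric(1))
  p <- vapply(profiles[ids], ppdr, numeric(1))
  S4Vectors::DataFrame(
    id = ids, ads = unname(a), ppdr = unname(p),
    tier = classifyTwoAxis(a, p, thresholds, rule),
    ads_only_tier = classifyAdsOnly(a, thresholds)
  )
}

#' Tier percentages from counts
#'
#' Percentages use the sum of the tier counts as denominator and are
#' reported to two decimals.
#'
#' @param counts named integer vector of per-tier counts.
#' @return named numeric vector of percentages summing to ~100.
#' @examples
#' tierPercentages(c(HighlyDisordered = 7970, HighlyOrdered = 19,
#'                   ModeratelyDisordered = 4371,
#'                   ModeratelyOrderedOrMildlyFlexible = 459))
#' @export
tierPercentages <- function(counts) {
  if (sum(counts) == 0) stop("no classified proteins")
  round(100 * counts / sum(counts), 2)
}

#' Proteome-level disorder summary
#'
#' Aggregates a [disorderSummary()] table: counts and percentages per tier,
#' plus proteome-level mean ADS and mean PPDR (means over proteins).
#'
#' @param summary a \code{DataFrame} from [disorderSummary()].
#' @return list with \code{n}, \code{counts}, \code{percentages},
#'   \code{mean_ads}, \code{mean_ppdr}.
#' @export
proteomeSummary <- function(summary) {
  counts <- vapply(.TIERS, function(t) sum(summary$tier == t), integer(1))
  list(n = nrow(summary), counts = counts,
       percentages = tierPercentages(counts),
       mean_ads = mean(summary$ads), mean_ppdr = mean(summary$ppdr))
}
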