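#' Load a Dietary Oxidative Balance Score component specification
#'
#' Validates a CSV/data.frame with columns `component`, `polarity`
#' (`anti_oxidant` / `pro_oxidant`), `rule` (`tertile` /
#' `alcohol_category`), and `transform` (`identity` / `log`).
#'
#' @param source path to a CSV file, or a data.frame with the same columns.
#' @return validated data.frame of class `dobs_spec`.
#' @seealso [dobs_reference()] for the bundled 17-nutrient spec.
#' @export
load_dobs_spec <- function(source) {
  tab <- if (is.data.frame(source)) source else {
    if (!file.exists(source)) fail("DOBS spec file not found: %s", source)
    read.csv(source, stringsAsFactors = FALSE)
  }
  need <- c("component", "polarity", "rule", "transform")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    fail("DOBS spec is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(tab) < 1L) fail("DOBS spec has no rows")
  if (anyDuplicated(tab$component))
    fail("duplicate DOBS component(s)")
  if (!all(tab$polarity %in% c("anti_oxidant", "pro_oxidant")))
    fail("polarity must be anti_oxidant or pro_oxidant")
  if (!all(tab$rule %in% c("tertile", "alcohol_category")))
    fail("rule must be tertile or alcohol_category")
  if (!all(tab$transform %in% c("identity", "log")))
    fail("transform must be identity or log")
  structure(tab[, need], class = c("dobs_spec", "data.frame"))
}

#' Bundled 17-nutrient DOBS specification
#'
#' 14 anti-oxidant nutrients (scored 1-3 ascending across sample tertiles)
#' and 3 pro-oxidants (scored inversely); alcohol is scored categorically
#' (nondrinker 3, nonheavy 2, heavy 1).  Vitamin C, beta-carotene, and
#' vitamin B12 carry a log transform.
#'
#' @return a `dobs_spec` data.frame with 17 rows.
#' @export
dobs_reference <- function() {
  load_dobs_spec(system.file("extdata", "dobs_components.csv",
                             package = "dietscores", mustWork = TRUE))
}

#' Assign sample tertiles
#'
#' Cutpoints are the 33.33% and 66.67% quantiles of the supplied values
#' (linear-interpolation definition, `type = 7`; a survey-weighted variant
#' via [weighted_quantile()] is available with `weights`).  Values at or
#' below the first cutpoint get label 1, values above the second get 3.
#' Ties at a cutpoint go to the lower tertile.
#'
#' @param values numeric vector with at least 3 finite values.
#' @param weights optional survey weights for weighted cutpoints.
#' @return integer vector of labels in \{1, 2, 3\} (NA where `values` is NA),
#'   with the cutpoints attached as attribute `"cutpoints"`.
#' @export
assign_tertiles <- function(values, weights = NULL) {
  fin <- values[is.finite(values)]
  if (length(fin) < 3L) fail("need at least 3 finite values for tertiles")
  q <- if (is.null(weights)) {
    quantile(fin, c(1, 2) / 3, type = 7, names = FALSE)
  } else {
    weighted_quantile(values, weights, c(1, 2) / 3)
  }
  if (diff(q) <= 0 && length(unique(fin)) == 1L)
    fail("degenerate tertiles: all values identical")
  lab <- ifelse(values <= q[1], 1L, ifelse(values <= q[2], 2L, 3L))
  structure(as.integer(lab), cutpoints = q)
}

alcohol_category_score <- function(grams, heavy_cut = 15) {
  if (any(grams < 0, na.rm = TRUE)) fail("negative alcohol intake")
  ifelse(grams == 0, 3L, ifelse(grams < heavy_cut, 2L, 1L))
}

#' Score one DOBS component
#'
#' Anti-oxidants take their tertile label (1 = lowest intake, 3 = highest);
#' pro-oxidants are scored inversely (4 - tertile).  The `alcohol_category`
#' rule scores nondrinkers (0 g/day) 3, nonheavy drinkers 2, and heavy
#' drinkers (>= 15 g/day for women) 1.
#'
#' @param values numeric daily intakes.
#' @param polarity `"anti_oxidant"` or `"pro_oxidant"`.
#' @param rule `"tertile"` or `"alcohol_category"`.
#' @param transform `"identity"` or `"log"` (log1p applied before tertile
#'   cutting; monotone, so tertile membership is unchanged — retained for
#'   spec fidelity and non-quantile extensions).
#' @param weights optional survey weights for weighted tertile cutpoints.
#' @return integer scores in \{1, 2, 3\}.
#' @export
score_component <- function(values, polarity = c("anti_oxidant", "pro_oxidant"),
                            rule = c("tertile", "alcohol_category"),
                            transform = c("identity", "log"), weights = NULL) {
  polarity <- match.arg(polarity)
  rule <- match.arg(rule)
  transform <- match.arg(transform)
  if (any(values < 0, na.rm = TRUE)) fail("negative intake")
  if (rule == "alcohol_category") {
    s <- alcohol_category_score(values)
    # categorical alcohol is inherently a pro-oxidant coding (high intake = 1)
    return(s)
  }
  v <- if (transform == "log") log1p(values) else values
  t3 <- assign_tertiles(v, weights)
  if (polarity == "anti_oxidant") t3 else 4L - t3
}

#' Compute the Dietary Oxidative Balance Score
#'
#' Applies each component's transform and scoring rule and sums the
#' per-component scores.  With the bundled 17-component spec the total lies
#' in 17..51; higher DOBS indicates a more anti-oxidative diet.
#'
#' @param intakes data.frame with `participant_id` plus one numeric column
#'   per spec component.
#' @param spec a `dobs_spec` (default [dobs_reference()]).
#' @param weights optional survey weights for weighted tertile cutpoints.
#' @return data.frame of class `dobs_scores`: `participant_id`, a score
#'   column per component, and `dobs`.
#' @export
compute_dobs <- function(intakes, spec = dobs_reference(), weights = NULL) {
  spec <- load_dobs_spec(spec)
  if (!"participant_id" %in% names(intakes))
    fail("`intakes` must have a participant_id column")
  miss <- setdiff(spec$component, names(intakes))
  if (length(miss))
    fail("intake table is missing DOBS component(s): %s", paste(miss, collapse = ", "))
  scores <- matrix(NA_integer_, nrow(intakes), nrow(spec),
                   dimnames = list(NULL, spec$component))
  for (j in seq_len(nrow(spec))) {
    scores[, j] <- score_component(intakes[[spec$component[j]]],
                                   spec$polarity[j], spec$rule[j],
                                   spec$transform[j], weights)
  }
  out <- data.frame(participant_id = intakes$participant_id, scores,
                    check.names = FALSE)
  out$dobs <- as.integer(rowSums(scores))
  structure(out, class = c("dobs_scores", "data.frame"))
}

#' Joint DII & DOBS diet classification
#'
#' Participants in the top DII tertile *and* the bottom DOBS tertile form the
#' pro-inflammatory/pro-oxidative group; those in the bottom DII tertile and
#' the top DOBS tertile form the anti-inflammatory/anti-oxidative group;
#' everyone else is the composite group.
#'
#' @param dii numeric DII values.
#' @param dobs numeric DOBS values.
#' @param weights optional survey weights for weighted tertile cutpoints.
#' @return factor with levels `pro_inflammatory_pro_oxidative`,
#'   `anti_inflammatory_anti_oxidative`, `composite`.
#' @export
classify_diet <- function(dii, dobs, weights = NULL) {
  if (length(dii) != length(dobs)) fail("dii and dobs must have equal length")
  t_dii <- assign_tertiles(dii, weights)
  t_dobs <- assign_tertiles(dobs, weights)
  lab <- ifelse(t_dii == 3L & t_dobs == 1L, "pro_inflammatory_pro_oxidative",
         ifelse(t_dii == 1L & t_dobs == 3L, "anti_inflammatory_anti_oxidative",
                "composite"))
  factor(lab, levels = c("pro_inflammatory_pro_oxidative",
                         "anti_inflammatory_anti_oxidative", "composite"))
}
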