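#' Collapse raw cloze responses into stem counts
#'
#' Cloze responses are normalized to lower case and morphological variants are
#' collapsed onto a common stem using a caller-supplied `stem_map` (for
#' example, mapping "sonnenschirm" onto "schirm"). Tokens absent from the map
#' are kept as-is; empty strings and `NA` (omitted responses) are dropped
#' before the respondent count is computed, so cloze proportions are taken out
#' of the respondents who actually gave a word. No language-specific stemmer
#' is built in.
#'
#' @param raw_tokens character vector of raw responses (one per respondent).
#' @param stem_map named character vector mapping token -> stem; identity for
#'   unmapped tokens. `NULL` means identity for all.
#' @param item_id,condition_label optional identifiers carried on the result.
#' @return an object of class `cloze_responses`: list with `item_id`,
#'   `condition_label`, `responses` (stem-collapsed tokens), `counts` (named
#'   integer vector) and `n_respondents`.
#' @export
#' @examples
#' collapse_responses(c(rep("Schirm", 5), rep("Sonnenschirm", 4), "Hut"),
#'                    c(sonnenschirm = "schirm"))
collapse_responses <- function(raw_tokens, stem_map = NULL,
                               item_id = NA_character_,
                               condition_label = NA_character_) {
  tok <- tolower(as.character(raw_tokens))
  tok <- tok[!is.na(tok) & nzchar(tok)]
  if (length(tok) == 0) stop("no responses")
  if (!is.null(stem_map)) {
    names(stem_map) <- tolower(names(stem_map))
    stem_map[] <- tolower(stem_map)
    hit <- tok %in% names(stem_map)
    tok[hit] <- unname(stem_map[tok[hit]])
  }
  counts <- table(tok)
  structure(
    list(item_id = item_id, condition_label = condition_label,
         responses = tok,
         counts = setNames(as.integer(counts), names(counts)),
         n_respondents = length(tok)),
    class = "cloze_responses")
}

#' Cloze probability of a target stem
#'
#' The proportion of respondents who completed the context with the target
#' word or word stem. A target absent from the counts has probability 0.
#'
#' @param counts named integer vector of stem counts (or a `cloze_responses`).
#' @param target target stem.
#' @param n number of respondents; must equal `sum(counts)`.
#' @return proportion in `[0, 1]`.
#' @export
cloze_probability <- function(counts, target, n) {
  if (inherits(counts, "cloze_responses")) counts <- counts$counts
  stopifnot_scalar(n, "n")
  if (n <= 0) stop("n must be positive")
  if (sum(counts) != n) stop("sum of counts (", sum(counts),
                             ") does not equal n (", n, ")")
  k <- counts[target]
  if (is.na(k)) k <- 0
  unname(k / n)
}

#' Laplace-smoothed log2 cloze probability
#'
#' Additive smoothing with pseudocounts of one on the two outcomes
#' "target given" vs "target not given": `log2((k + 1) / (n + 2))`. The
#' result is strictly negative (smoothed probability never reaches 1), which
#' keeps the log defined for zero-cloze targets.
#'
#' @param k_target number of respondents who gave the target (0..n).
#' @param n number of respondents.
#' @return negative real, bits-scale log probability.
#' @export
smoothed_log2_cloze <- function(k_target, n) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(k_target < 0) || any(k_target > n)) stop("k_target must be in [0, n]")
  log2((k_target + 1) / (n + 2))
}

#' Shannon entropy of a cloze distribution, in bits
#'
#' `-sum(p * log2(p))` with zero-probability terms contributing zero. Low
#' entropy means a strongly constraining context (responses concentrated on
#' few completions); high entropy means weak constraint.
#'
#' @param probabilities nonnegative vector summing to 1 (tolerance `1e-8`).
#' @return nonnegative entropy in bits; 0 iff one probability equals 1.
#' @export
#' @examples
#' entropy_bits(c(0.9, 0.1))  # 0.47 to two decimals
entropy_bits <- function(probabilities) {
  p <- probabilities
  if (any(p < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(p) - 1) > 1e-8) stop("probabilities not normalized")
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Center a predictor on the mean of the rows entering a model
#'
#' Centering is always done over exactly the rows included in the target
#' analysis, not over the full item set: the two collapsed-condition analyses
#' use different row subsets and therefore different centers.
#'
#' @param values numeric vector (nonempty).
#' @return `values - mean(values)`.
#' @export
center_predictor <- function(values) {
  if (length(values) == 0) stop("cannot center an empty vector")
  values - mean(values)
}

#' Build the predictor table from cloze responses and target words
#'
#' One row per item x condition with the target count, raw cloze proportion,
#' Laplace-smoothed log2 cloze, and response entropy in bits. Centered
#' predictor columns are added over all rows of the table; re-center with
#' [center_predictor()] on the analysis subset before modelling (the trial
#' table builder does this automatically).
#'
#' @param responses data.frame with columns `item_id`, `condition`,
#'   `respondent_id`, `response_token`, or a list of `cloze_responses`.
#' @param targets data.frame with columns `item_id`, `condition`,
#'   `target_token`.
#' @param stem_map optional token -> stem map passed to [collapse_responses()].
#' @return data.frame of class `predictor_table` with columns `item_id`,
#'   `condition`, `target_token`, `k_target`, `n_respondents`,
#'   `proportion_target`, `log2_cloze_smoothed`, `entropy_bits`,
#'   `log2_cloze_centered`, `entropy_centered`.
#' @export
build_predictor_table <- function(responses, targets, stem_map = NULL) {
  if (is.data.frame(responses)) {
    need <- c("item_id", "condition", "response_token")
    if (!all(need %in% names(responses)))
      stop("responses must have columns ", paste(need, collapse = ", "))
    keys <- split(responses,
                  list(responses$item_id, responses$condition), drop = TRUE)
    sets <- lapply(keys, function(d)
      collapse_responses(d$response_token, stem_map,
                         item_id = as.character(d$item_id[1]),
                         condition_label = as.character(d$condition[1])))
  } else {
    sets <- responses
  }
  tg <- targets
  tg$item_id <- as.character(tg$item_id)
  tg$condition <- as.character(tg$condition)
  rows <- lapply(sets, function(s) {
    hit <- tg$item_id == s$item_id & tg$condition == s$condition_label
    if (!any(hit)) stop("no target word for item ", s$item_id,
                        " condition ", s$condition_label)
    target <- tolower(tg$target_token[which(hit)[1]])
    n <- s$n_respondents
    k <- if (target %in% names(s$counts)) s$counts[[target]] else 0L
    p <- s$counts / n
    data.frame(item_id = s$item_id, condition = s$condition_label,
               target_token = target, k_target = k, n_respondents = n,
               proportion_target = k / n,
               log2_cloze_smoothed = smoothed_log2_cloze(k, n),
               entropy_bits = entropy_bits(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$log2_cloze_centered <- center_predictor(out$log2_cloze_smoothed)
  out$entropy_centered <- center_predictor(out$entropy_bits)
  class(out) <- c("predictor_table", "data.frame")
  out
}

#' Read cloze responses / write a predictor table (TSV)
#'
#' @param file path to a TSV with columns `item_id`, `condition`,
#'   `respondent_id`, `response_token`.
#' @return data.frame of responses.
#' @export
read_cloze_responses <- function(file) {
  d <- data.table::fread(file, sep = "\t", colClasses = "character",
                         data.table = FALSE)
  need <- c("item_id", "condition", "respondent_id", "response_token")
  if (!all(need %in% names(d)))
    stop("missing columns: ", paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' @rdname read_cloze_responses
#' @param table a `predictor_table`.
#' @export
write_predictor_table <- function(table, file) {
  data.table::fwrite(as.data.frame(table), file, sep = "\t")
  invisible(file)
}
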