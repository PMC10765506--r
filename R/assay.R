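#' Ordinal coding of the five phenotypic screening assays
#'
#' A yeast isolate's plate-assay results are condensed into a five-digit
#' ordinal phenotype code, one digit per assay, ordered by oenological
#' priority: killer toxin reaction, H2S production, acetic acid
#' production, SO2 resistance and beta-glucosidase activity.  The coding
#' scheme is:
#'
#' * digit 1 (killer): 1 = neutral, 2 = sensitive.  Killer-positive
#'   isolates have no code and raise an error unless
#'   `allow_killer_positive = TRUE`, which maps them to 3.
#' * digit 2 (H2S): 0 = no production up to 3 = very high production,
#'   collapsed from the day-2/5/8 colour scores by `policy`.
#' * digit 3 (acetic acid): 0 = production, 1 = no production (0 is the
#'   undesirable state).
#' * digit 4 (SO2): 0 = no resistance, 1 = growth at 100--300 mg/L free
#'   SO2 only, 2 = growth at 400 or 500 mg/L.
#' * digit 5 (beta-glucosidase): 0 = positive, 1 = negative.
#'
#' @param killer one of `"neutral"`, `"sensitive"`, `"killer_positive"`.
#' @param allow_killer_positive map killer-positive isolates to digit 3
#'   instead of failing.
#' @return an integer digit.
#' @seealso [encode_phenotype()] for whole-panel coding,
#'   [phenotype_codes()] for data frames.
#' @examples
#' encode_killer("neutral")     # 1
#' encode_killer("sensitive")   # 2
#' @export
encode_killer <- function(killer, allow_killer_positive = FALSE) {
  killer <- match.arg(killer, c("neutral", "sensitive", "killer_positive"))
  if (killer == "killer_positive") {
    if (!allow_killer_positive)
      .oeno_stop(
        "killer-positive isolates have no code in the scheme; set allow_killer_positive = TRUE to map them to 3",
        "oenotype_unsupported_phenotype")
    return(3L)
  }
  if (killer == "neutral") 1L else 2L
}

#' Collapse the H2S time series to a single digit
#'
#' Colony browning on bismuth agar is scored 0 (white, no production) to
#' 3 (dark brown) after 2, 5 and 8 days of incubation.  The code uses a
#' single digit; `policy` selects how the three readings collapse:
#' `"day8"` (final reading, the default), `"max"`, or `"mean"` (rounded).
#'
#' @param h2s_scores named numeric vector or list with entries for days
#'   `"2"`, `"5"` and `"8"`, each score in 0..3.
#' @param policy collapse policy.
#' @return integer digit in 0..3.
#' @examples
#' encode_h2s(c("2" = 1, "5" = 2, "8" = 3))                  # 3
#' encode_h2s(c("2" = 0, "5" = 2, "8" = 1), policy = "max")  # 2
#' @export
encode_h2s <- function(h2s_scores, policy = c("day8", "max", "mean")) {
  policy <- match.arg(policy)
  h2s_scores <- unlist(h2s_scores)
  want <- as.character(.h2s_days)
  if (!all(want %in% names(h2s_scores)) || anyNA(h2s_scores[want]))
    .oeno_stop("H2S scores must be present for days 2, 5 and 8",
               "oenotype_incomplete_assay")
  s <- as.numeric(h2s_scores[want])
  if (any(s < 0 | s > 3 | s != round(s)))
    .oeno_stop("H2S scores must be integers in 0..3",
               "oenotype_incomplete_assay")
  out <- switch(policy,
    day8 = s[3L],
    max  = max(s),
    mean = round(mean(s)))
  as.integer(out)
}

#' @rdname encode_killer
#' @param acetic `"producer"` or `"non_producer"`.
#' @export
encode_acetic <- function(acetic) {
  acetic <- match.arg(acetic, c("producer", "non_producer"))
  if (acetic == "producer") 0L else 1L
}

#' @rdname encode_killer
#' @param digit integer digit to decode back to the assay state.
#' @export
decode_acetic <- function(digit) {
  stopifnot(digit %in% 0:1)
  if (digit == 0L) "producer" else "non_producer"
}

#' Code SO2 resistance from the growth series
#'
#' Isolates are plated at 0, 100, 200, 300, 400 and 500 mg/L free SO2.
#' The digit is derived from the highest dose with growth: 2 if the
#' isolate grew at 400 or 500 mg/L, 1 if it grew at any of 100--300 mg/L
#' only, 0 if it grew at 0 mg/L only.  Non-monotone profiles (growth at
#' a high dose but not at a lower one, a plate artifact) warn and are
#' coded from the highest growth dose.
#'
#' @param so2_growth named logical vector over the six doses (names
#'   `"0"`, `"100"`, ..., `"500"`); growth at 0 must be `TRUE`.
#' @return integer digit in 0..2.
#' @examples
#' encode_so2(setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
#'                     c(0, 100, 200, 300, 400, 500)))  # 1
#' @export
encode_so2 <- function(so2_growth) {
  so2_growth <- unlist(so2_growth)
  want <- as.character(.so2_doses)
  if (!all(want %in% names(so2_growth)) || anyNA(so2_growth[want]))
    .oeno_stop("SO2 growth must be present for all six doses",
               "oenotype_incomplete_assay")
  g <- as.logical(so2_growth[want])
  if (!g[1L])
    .oeno_stop("no growth at 0 mg/L SO2: not a viable isolate record",
               "oenotype_incomplete_assay")
  grown <- .so2_doses[g]
  top <- max(grown)
  # monotone profile grows at every dose below its maximum
  if (!all(.so2_doses[.so2_doses <= top] %in% grown))
    warning("non-monotone SO2 growth profile; coding from highest growth dose",
            call. = FALSE)
  if (top >= 400L) 2L else if (top >= 100L) 1L else 0L
}

#' @rdname encode_killer
#' @param bglu `"positive"` or `"negative"`.
#' @export
encode_bglu <- function(bglu) {
  bglu <- match.arg(bglu, c("positive", "negative"))
  if (bglu == "positive") 0L else 1L
}

#' @rdname encode_killer
#' @export
decode_bglu <- function(digit) {
  stopifnot(digit %in% 0:1)
  if (digit == 0L) "positive" else "negative"
}

#' Encode a full assay panel into a phenotype code
#'
#' @param panel a list with components `killer`, `h2s_scores`, `acetic`,
#'   `so2_growth` and `bglu` as accepted by the digit encoders.
#' @param policy H2S collapse policy, see [encode_h2s()].
#' @param allow_killer_positive see [encode_killer()].
#' @return integer vector of length 5 named killer/h2s/acetic/so2/bglu.
#' @examples
#' panel <- list(killer = "neutral",
#'               h2s_scores = c("2" = 0, "5" = 1, "8" = 1),
#'               acetic = "producer",
#'               so2_growth = setNames(rep(TRUE, 6), c(0, 100, 200, 300, 400, 500)),
#'               bglu = "negative")
#' encode_phenotype(panel)  # 1 1 0 2 1
#' @export
encode_phenotype <- function(panel, policy = "day8",
                             allow_killer_positive = FALSE) {
  code <- c(
    encode_killer(panel$killer, allow_killer_positive),
    encode_h2s(panel$h2s_scores, policy),
    encode_acetic(panel$acetic),
    encode_so2(panel$so2_growth),
    encode_bglu(panel$bglu))
  names(code) <- .digit_names
  code
}

#' Read an assay table and encode all isolates
#'
#' The assay CSV dialect has one row per isolate with columns
#' `isolate_id, sample_id, region, variety, wine_type, vintage, species,
#' killer, h2s_d2, h2s_d5, h2s_d8, acetic, so2_100, ..., so2_500, bglu`
#' (growth at 0 mg/L SO2 is implied).  `phenotype_codes()` appends the
#' five digit columns `code_killer ... code_bglu` and a joined display
#' string `phenotype`.
#'
#' @param path path to the assay CSV.
#' @return a data frame.
#' @export
read_assay_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("isolate_id", "killer", "h2s_d2", "h2s_d5", "h2s_d8", "acetic",
            paste0("so2_", .so2_doses[-1L]), "bglu")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .oeno_stop(paste("assay CSV missing columns:", paste(miss, collapse = ", ")),
               "oenotype_bad_input")
  if (anyDuplicated(df$isolate_id))
    .oeno_stop("duplicated isolate_id in assay CSV", "oenotype_bad_input")
  if ("vintage" %in% names(df) &&
      any(df$vintage < 1900 | df$vintage > 2100, na.rm = TRUE))
    .oeno_stop("vintage outside [1900, 2100]", "oenotype_bad_input")
  df
}

#' @rdname read_assay_csv
#' @param df assay data frame as returned by [read_assay_csv()].
#' @param policy,allow_killer_positive passed to the digit encoders.
#' @export
phenotype_codes <- function(df, policy = "day8",
                            allow_killer_positive = FALSE) {
  codes <- t(vapply(seq_len(nrow(df)), function(i) {
    so2 <- c(TRUE, as.logical(unlist(df[i, paste0("so2_", .so2_doses[-1L])])))
    panel <- list(
      killer = df$killer[i],
      h2s_scores = setNames(as.numeric(df[i, c("h2s_d2", "h2s_d5", "h2s_d8")]),
                            .h2s_days),
      acetic = df$acetic[i],
      so2_growth = setNames(so2, .so2_doses),
      bglu = df$bglu[i])
    encode_phenotype(panel, policy, allow_killer_positive)
  }, integer(5L)))
  colnames(codes) <- paste0("code_", .digit_names)
  out <- cbind(df, codes)
  out$phenotype <- apply(codes, 1L, paste, collapse = "")
  out
}

#' Tabulate distinct phenotype codes
#'
#' @param codes an integer matrix of phenotype codes (isolates in rows,
#'   the five digits in columns), or a data frame carrying
#'   `code_*` columns as produced by [phenotype_codes()].
#' @return a data frame with the five digit columns, the display string
#'   and the isolate count per distinct code, in lexicographic order.
#' @export
distinct_phenotypes <- function(codes) {
  codes <- .as_code_matrix(codes)
  if (nrow(codes) == 0L)
    .oeno_stop("empty dataset", "oenotype_empty_dataset")
  key <- apply(codes, 1L, paste, collapse = "")
  ord <- order(key)
  tab <- table(key)
  uk <- names(tab)
  first <- match(uk, key)
  out <- as.data.frame(codes[first, , drop = FALSE])
  names(out) <- paste0("code_", .digit_names)
  out$phenotype <- uk
  out$count <- as.integer(tab)
  rownames(out) <- NULL
  out
}

# accept either a bare 5-column matrix or a phenotype_codes() data frame
.as_code_matrix <- function(x) {
  if (is.data.frame(x)) {
    cols <- paste0("code_", .digit_names)
    if (!all(cols %in% names(x)))
      .oeno_stop("data frame lacks code_* columns; run phenotype_codes() first",
                 "oenotype_bad_input")
    x <- as.matrix(x[, cols])
  }
  x <- as.matrix(x)
  if (ncol(x) != 5L)
    .oeno_stop("phenotype codes have exactly 5 digits", "oenotype_bad_input")
  storage.mode(x) <- "integer"
  bad <- sweep(x, 2L, .digit_lo, "<") | sweep(x, 2L, .digit_hi, ">")
  if (any(bad))
    .oeno_stop("phenotype digit outside its ordinal range", "oenotype_bad_input")
  colnames(x) <- .digit_names
  x
}
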