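#' Load the shipped (or user-supplied) lexicons
#'
#' Reads the easy-word list used for the verbal-ability indicator and the
#' five category word lists (conjunctions, negations, discrepancies,
#' tentative words, differentiation/exclusion words). Lists are plain text,
#' one entry per line, lowercase; a trailing `*` marks a stem that matches
#' any token beginning with it. The shipped easy-word list is an open
#' approximation of the classic ~3000-word fourth-grade familiarity list,
#' and the category lists are open approximations of the standard
#' closed-vocabulary text-analysis categories; both can be replaced by
#' pointing `dir` at files with the same names.
#'
#' @param dir directory containing `dale_chall.txt`, `conjunctions.txt`,
#'   `negations.txt`, `discrepancies.txt`, `tentative.txt`, `exclusion.txt`.
#' @return object of class `"lexicons"`: a named list of character vectors
#'   (`easy`, `CON`, `NEG`, `DIS`, `TEN`, `EXC`).
#' @export
load_lexicons <- function(dir = system.file("extdata", "lexicons",
                                            package = "resperr")) {
  files <- c(easy = "dale_chall.txt", CON = "conjunctions.txt",
             NEG = "negations.txt", DIS = "discrepancies.txt",
             TEN = "tentative.txt", EXC = "exclusion.txt")
  out <- lapply(files, function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("lexicon file not found: ", p)
    unique(tolower(trimws(readLines(p, warn = FALSE))))
  })
  out <- lapply(out, function(w) w[nzchar(w)])
  class(out) <- "lexicons"
  out
}

#' Tokenize item text
#'
#' Lowercases, strips punctuation except intra-word apostrophes and hyphens
#' (hyphenated forms count as a single token), and splits on whitespace.
#'
#' @param text character scalar or vector.
#' @return character vector of tokens (for a scalar input), or a list.
#' @export
tokenize_item <- function(text) {
  one <- function(s) {
    s <- tolower(s)
    s <- gsub("[^a-z0-9'-]+", " ", s)
    toks <- strsplit(trimws(s), "\\s+")[[1]]
    toks <- gsub("^['-]+|['-]+$", "", toks)
    toks[nzchar(toks)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

# does any token match the word/stem list?
match_lexicon <- function(tokens, lexicon) {
  stems <- lexicon[endsWith(lexicon, "*")]
  full <- setdiff(lexicon, stems)
  hit <- tokens %in% full
  for (st in substr(stems, 1L, nchar(stems) - 1L))
    hit <- hit | startsWith(tokens, st)
  hit
}

#' Word-count complexity indicator
#'
#' 1 if the item text has `threshold` (default 10) or more tokens.
#'
#' @param text item wording.
#' @param threshold word-count cutoff.
#' @return 0/1.
#' @export
word_count_indicator <- function(text, threshold = 10L) {
  toks <- tokenize_item(text)
  if (!length(toks)) stop("empty item text")
  as.integer(length(toks) >= threshold)
}

#' Verbal-ability (unfamiliar words) indicator
#'
#' 1 if `threshold` (default 2) or more tokens are absent from the easy-word
#' list; items with all words on the list or only one off-list word score 0.
#' Matching is case-insensitive on normalized tokens; purely numeric tokens
#' are treated as familiar.
#'
#' @param text item wording.
#' @param lexicons a [load_lexicons()] object.
#' @param threshold off-list word-count cutoff.
#' @return 0/1.
#' @export
dale_chall_indicator <- function(text, lexicons, threshold = 2L) {
  if (missing(lexicons) || is.null(lexicons)) stop("lexicons required")
  toks <- tokenize_item(text)
  if (!length(toks)) stop("empty item text")
  off <- !(toks %in% lexicons$easy) & !grepl("^[0-9]+$", toks)
  as.integer(sum(off) >= threshold)
}

#' Category word indicators (contained-any semantics)
#'
#' Five binaries: conjunctions (CON; e.g. if, whereas, because), negations
#' (NEG; e.g. no, not, never), discrepancies (DIS; e.g. should, would,
#' could), tentative words (TEN; e.g. maybe, perhaps), and
#' differentiation/exclusion words (EXC; e.g. but, else). Each is 1 iff any
#' token (or stem match) belongs to the category list.
#'
#' @inheritParams dale_chall_indicator
#' @return named integer vector `c(CON, NEG, DIS, TEN, EXC)`.
#' @export
liwc_style_indicators <- function(text, lexicons) {
  toks <- tokenize_item(text)
  vapply(c("CON", "NEG", "DIS", "TEN", "EXC"),
         function(k) as.integer(any(match_lexicon(toks, lexicons[[k]]))),
         integer(1))
}

#' Validate and attach precomputed clarity flags
#'
#' The three clarity indicators (unfamiliar technical terms UTT, vague
#' relative terms VRT, vague noun phrases VNP) come from an external
#' question-understanding tool and are ingested as data, not recomputed.
#'
#' @param items data.frame with an `item_id` column.
#' @param flags data.frame with columns `item_id`, `UTT`, `VRT`, `VNP`
#'   (values 0/1), or `NULL`.
#' @param strict if `TRUE` (default), a missing table or missing items are
#'   errors; if `FALSE`, absent flags default to 0 with a warning.
#' @return data.frame `item_id, UTT, VRT, VNP` aligned with `items`.
#' @export
load_precomputed_flags <- function(items, flags = NULL, strict = TRUE) {
  ids <- items$item_id
  if (is.null(flags)) {
    if (strict) stop("precomputed clarity flags required (strict = TRUE)")
    warning("no clarity flags supplied; UTT/VRT/VNP default to 0")
    return(data.frame(item_id = ids, UTT = 0L, VRT = 0L, VNP = 0L))
  }
  need <- c("item_id", "UTT", "VRT", "VNP")
  if (!all(need %in% names(flags)))
    stop("flags table must have columns: ", paste(need, collapse = ", "))
  bad <- !vapply(ids, function(i) i %in% flags$item_id, TRUE)
  if (any(bad)) {
    if (strict) stop("flags missing for item(s): ",
                     paste(ids[bad], collapse = ", "))
    warning("flags missing for ", sum(bad), " item(s); defaulting to 0")
  }
  f <- flags[match(ids, flags$item_id), need]
  for (cn in c("UTT", "VRT", "VNP")) {
    f[[cn]][is.na(f[[cn]])] <- 0L
    off <- !(f[[cn]] %in% c(0L, 1L))
    if (any(off))
      stop("non-binary ", cn, " value for item(s): ",
           paste(ids[off], collapse = ", "))
  }
  f$item_id <- ids
  rownames(f) <- NULL
  f
}

#' Composite complexity and five-level bins
#'
#' The composite is the sum of the ten binary indicators (range 0-10). Bins
#' follow the partition 0-1, 2-3, 4-5, 6-7, 8-9 (a composite of 10, which no
#' realistic item bank reaches, is assigned to the top bin).
#'
#' @param profile data.frame containing the ten indicator columns
#'   `WC, DC, UTT, VRT, VNP, CON, NEG, DIS, TEN, EXC`.
#' @return `profile` with `composite` and `bin` columns appended.
#' @export
composite_and_bins <- function(profile) {
  ind <- c("WC", "DC", "UTT", "VRT", "VNP", "CON", "NEG", "DIS", "TEN", "EXC")
  miss <- setdiff(ind, names(profile))
  if (length(miss)) stop("missing indicator column(s): ",
                         paste(miss, collapse = ", "))
  profile$composite <- as.integer(rowSums(profile[ind]))
  profile$bin <- pmin(profile$composite %/% 2L + 1L, 5L)
  profile
}

#' Code the ten complexity indicators for an item bank
#'
#' Applies the word-count, easy-word-list, and category-word indicators to
#' each item's text, attaches the three precomputed clarity flags, and
#' returns the full complexity profile with composite and bin.
#'
#' @param items data.frame with columns `item_id`, `item_text`.
#' @param flags optional data.frame of precomputed `UTT/VRT/VNP` flags (see
#'   [load_precomputed_flags()]); if `NULL` and `items` itself carries those
#'   columns, they are used.
#' @param lexicons a [load_lexicons()] object.
#' @param wc_threshold,dc_threshold cutoffs for the word-count and off-list
#'   indicators. The printed defaults (10 words; 2 off-list words) come from
#'   median splits in the motivating item bank; set
#'   `recompute_medians = TRUE` to re-derive them from the supplied items.
#' @param recompute_medians recompute both cutoffs as medians of the supplied
#'   item set.
#' @param strict_flags passed to [load_precomputed_flags()].
#' @return data.frame of class `"complexity_profile"`: `item_id`, the ten
#'   indicators, `composite`, `bin`.
#' @export
code_complexity <- function(items, flags = NULL,
                            lexicons = load_lexicons(),
                            wc_threshold = 10L, dc_threshold = 2L,
                            recompute_medians = FALSE, strict_flags = FALSE) {
  stopifnot(all(c("item_id", "item_text") %in% names(items)))
  txt <- trimws(items$item_text)
  if (any(!nzchar(txt))) stop("empty item text for item(s): ",
                              paste(items$item_id[!nzchar(txt)], collapse = ", "))
  if (recompute_medians) {
    wc <- vapply(txt, function(t) length(tokenize_item(t)), 1L)
    off <- vapply(txt, function(t) {
      toks <- tokenize_item(t)
      sum(!(toks %in% lexicons$easy) & !grepl("^[0-9]+$", toks))
    }, 1L)
    wc_threshold <- stats::median(wc)
    dc_threshold <- max(1L, stats::median(off))
  }
  if (is.null(flags) && all(c("UTT", "VRT", "VNP") %in% names(items)))
    flags <- items[c("item_id", "UTT", "VRT", "VNP")]
  fl <- load_precomputed_flags(items, flags, strict = strict_flags)
  cat5 <- t(vapply(txt, liwc_style_indicators, integer(5),
                   lexicons = lexicons))
  prof <- data.frame(
    item_id = items$item_id,
    WC = vapply(txt, word_count_indicator, 1L, threshold = wc_threshold),
    DC = vapply(txt, dale_chall_indicator, 1L, lexicons = lexicons,
                threshold = dc_threshold),
    UTT = fl$UTT, VRT = fl$VRT, VNP = fl$VNP,
    CON = cat5[, "CON"], NEG = cat5[, "NEG"], DIS = cat5[, "DIS"],
    TEN = cat5[, "TEN"], EXC = cat5[, "EXC"])
  rownames(prof) <- NULL
  prof <- composite_and_bins(prof)
  class(prof) <- c("complexity_profile", "data.frame")
  prof
}

#' @export
print.complexity_profile <- function(x, ...) {
  cat("Complexity profile for", nrow(x), "items\n")
  cat("Composite: mean", round(mean(x$composite), 2),
      " SD", round(sd(x$composite), 2),
      " range", paste(range(x$composite), collapse = "-"), "\n")
  ind <- c("WC", "DC", "UTT", "VRT", "VNP", "CON", "NEG", "DIS", "TEN", "EXC")
  pct <- round(100 * colMeans(as.data.frame(x)[ind]), 1)
  print(pct)
  invisible(x)
}
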