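#' Tokenize a sentence for word-overlap scoring
#'
#' Lowercases, strips punctuation (everything that is not a letter, digit, or
#' whitespace), and splits on whitespace. The empty string yields an empty
#' token vector.
#'
#' @param text character scalar.
#' @return character vector of tokens.
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  x <- tolower(text)
  x <- gsub("[^[:alnum:][:space:]]", " ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

# Longest matching contiguous block between a[alo:ahi] and b[blo:bhi].
# Ties broken by earliest start in `a`, then earliest start in `b`.
longest_match <- function(a, b, alo, ahi, blo, bhi) {
  best_i <- alo; best_j <- blo; best_len <- 0L
  if (ahi < alo || bhi < blo)
    return(list(i = best_i, j = best_j, len = best_len))
  # j2len[j] = length of longest run ending at (i, j)
  j2len <- integer(bhi)
  for (i in alo:ahi) {
    new_j2len <- integer(bhi)
    js <- which(b[blo:bhi] == a[i]) + blo - 1L
    for (j in js) {
      k <- if (j > blo) j2len[j - 1L] + 1L else 1L
      new_j2len[j] <- k
      if (k > best_len) {
        best_i <- i - k + 1L; best_j <- j - k + 1L; best_len <- k
      }
    }
    j2len <- new_j2len
  }
  list(i = best_i, j = best_j, len = best_len)
}

# Total matched element count of the Ratcliff-Obershelp recursion.
ro_matches <- function(a, b, alo, ahi, blo, bhi) {
  m <- longest_match(a, b, alo, ahi, blo, bhi)
  if (m$len == 0L) return(0L)
  m$len +
    ro_matches(a, b, alo, m$i - 1L, blo, m$j - 1L) +
    ro_matches(a, b, m$i + m$len, ahi, m$j + m$len, bhi)
}

#' Ratcliff-Obershelp similarity between two token sequences
#'
#' Recursively finds the longest matching contiguous block, then matches the
#' regions to its left and right, and returns `2 * M / T`, where `M` is the
#' total number of matched tokens and `T` the total number of tokens in both
#' sequences. Equals 1 for identical non-empty sequences and 0 for disjoint
#' vocabularies. No junk heuristics are applied.
#'
#' @param ref character vector of reference tokens.
#' @param resp character vector of response tokens.
#' @return similarity ratio in `[0, 1]` (1 when both sequences are empty).
#' @examples
#' sequence_similarity(c("the", "cat", "sat", "down"),
#'                     c("the", "cat", "down"))   # 6/7
#' @export
sequence_similarity <- function(ref, resp) {
  total <- length(ref) + length(resp)
  if (total == 0L) return(1)
  m <- ro_matches(ref, resp, 1L, length(ref), 1L, length(resp))
  2 * m / total
}

#' Score reference/response pairs from a data frame
#'
#' @param pairs data frame with columns `trial_id`, `reference`, `response`
#'   (raw strings; tokenized with [tokenize()]).
#' @return data frame of class-less scored responses: `trial_id`,
#'   `reference`, `response`, `score` in `[0, 1]`.
#' @export
score_responses <- function(pairs) {
  stopifnot(all(c("trial_id", "reference", "response") %in% names(pairs)))
  pairs$score <- mapply(function(r, s)
    sequence_similarity(tokenize(r), tokenize(s)),
    pairs$reference, pairs$response, USE.NAMES = FALSE)
  pairs
}

#' Read reference/response pairs from CSV
#' @param path CSV with columns `trial_id`, `reference`, `response`.
#' @return data frame ready for [score_responses()].
#' @export
read_response_pairs <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  stopifnot(all(c("trial_id", "reference", "response") %in% names(df)))
  df
}
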