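#' Encode a binary activity pattern as an integer code
#'
#' Activity patterns are vectors in \{-1, +1\}^K (+1 active, -1 inactive).
#' The canonical code sets bit \eqn{i} (value \eqn{2^{i-1}}) when network
#' \eqn{i} is active, giving a bijection between patterns and the integers
#' \code{0:(2^K - 1)}. Bit order follows the column order of the input time
#' series, so codes are reproducible bit-exactly for a fixed network roster.
#'
#' @param v Numeric vector with entries -1 or +1.
#' @return Integer in \code{[0, 2^K - 1]}.
#' @seealso [pattern_decode()], [all_patterns()]
#' @export
#' @examples
#' pattern_code(c(-1, -1, -1))        # 0
#' pattern_code(rep(1, 7))            # 127
pattern_code <- function(v) {
  stopifnot(is.numeric(v), length(v) >= 1)
  if (!all(v %in% c(-1, 1))) {
    stop("pattern entries must be -1 or +1")
  }
  as.integer(sum(2^(seq_along(v) - 1) * (v > 0)))
}

#' Decode an integer pattern code back to a +/-1 activity vector
#'
#' Inverse of [pattern_code()].
#'
#' @param code Integer in \code{[0, 2^K - 1]}.
#' @param K Number of networks.
#' @return Numeric vector of length \code{K} with entries -1/+1.
#' @export
pattern_decode <- function(code, K) {
  stopifnot(length(code) == 1, code >= 0, code < 2^K)
  ifelse(bitwAnd(as.integer(code), 2^(seq_len(K) - 1)) > 0, 1, -1)
}

#' All 2^K activity patterns in code order
#'
#' @param K Number of networks (capped at 20; all exhaustive operations are
#'   O(2^K)).
#' @return A \code{2^K x K} matrix of -1/+1 values; row \code{r} is the
#'   pattern with code \code{r - 1}.
#' @export
all_patterns <- function(K) {
  check_enumeration_cap(K)
  codes <- 0:(2^K - 1)
  vapply(seq_len(K), function(i) ifelse(bitwAnd(codes, 2^(i - 1)) > 0, 1, -1),
         numeric(2^K))
}

# Hard cap on exhaustive enumeration; everything downstream is O(2^K).
.ENUM_CAP <- 20L

check_enumeration_cap <- function(K) {
  stopifnot(is.numeric(K), length(K) == 1, K >= 1, K == round(K))
  if (K > .ENUM_CAP) {
    stop("K = ", K, " exceeds the enumeration cap of ", .ENUM_CAP,
         "; exhaustive landscape operations are O(2^K) and are not ",
         "supported above it", call. = FALSE)
  }
  invisible(as.integer(K))
}

# 2^K x K matrix of 1-based row indices of the Hamming-1 neighbours of each
# pattern; column b flips bit b.
neighbour_index <- function(K) {
  codes <- 0:(2^K - 1)
  vapply(seq_len(K), function(b) bitwXor(codes, 2^(b - 1)) + 1L,
         integer(2^K))
}
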