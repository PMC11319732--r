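#' Frame peptides into fixed-width token strings
#'
#' A peptide is wrapped in terminus markers and right-padded with blanks:
#' `"(" + peptide + ")" + "X" * (max_len - length)`, giving a fixed width of
#' `max_len + 2` (13 for the default 11-residue maximum). Marking the
#' termini lets the model distinguish sequence ends from padding, which
#' matters once the frame is shifted inside a wider vector.
#'
#' @param peptides Character vector, lengths 5 to `max_len`, over the
#'   16-letter alphabet.
#' @param max_len Maximum peptide length (default 11).
#' @return Character vector of framed strings, width `max_len + 2`.
#' @examples
#' frame_peptide("LPGVQG")    # "(LPGVQG)XXXXX"
#' frame_peptide("GNFAYQRDG") # "(GNFAYQRDG)XX"
#' @export
frame_peptide <- function(peptides, max_len = 11L) {
  assert_alphabet(peptides, "peptides")
  len <- nchar(peptides)
  if (any(len < 5 | len > max_len)) {
    stop(sprintf("peptide lengths must be 5-%d; offending: %s", max_len,
                 paste(utils::head(peptides[len < 5 | len > max_len], 3),
                       collapse = ", ")), call. = FALSE)
  }
  paste0("(", peptides, ")",
         strrep("X", max_len - len))
}

#' Expand a framed sequence into 6 register-shifted copies
#'
#' Each framed string is placed at 6 different offsets inside an extended
#' vector (width + 5), padded with blanks on both sides: copy k (k = 0..5)
#' is `"X"*k + framed + "X"*(5-k)`. All copies carry the same binding
#' target during training, forcing the network to learn the motif
#' independently of its register.
#'
#' @param framed Character vector of framed strings (shift 0), all the same
#'   width.
#' @param n_frames Number of registers (default 6).
#' @return Character matrix with one row per input and `n_frames` columns;
#'   all entries share width `nchar(framed) + n_frames - 1`.
#' @export
shift_frames <- function(framed, n_frames = 6L) {
  w <- unique(nchar(framed))
  if (length(w) != 1) stop("framed strings must share one width",
                           call. = FALSE)
  shifts <- 0:(n_frames - 1L)
  out <- vapply(shifts, function(k) {
    paste0(strrep("X", k), framed, strrep("X", n_frames - 1L - k))
  }, character(length(framed)))
  matrix(out, nrow = length(framed), ncol = n_frames,
         dimnames = list(NULL, paste0("shift", shifts)))
}

#' Strip framing to recover the peptide
#'
#' Inverse of [frame_peptide()] composed with any register shift: removes
#' padding blanks and the terminus markers.
#'
#' @param framed Character vector of framed (possibly shifted) strings.
#' @return Character vector of bare peptides.
#' @export
unframe_peptide <- function(framed) {
  sub("^X*\\((.*)\\)X*$", "\\1", framed)
}

#' Tokenize framed strings to an integer index matrix
#'
#' Maps each character of each framed string to its index in the frozen
#' 19-token alphabet. This matrix is the model input; the one-hot expansion
#' is applied implicitly inside the network.
#'
#' @param framed Character vector of equal-width framed strings.
#' @return Integer matrix (n x width), 1-based indices into
#'   [token_alphabet()].
#' @export
encode_tokens <- function(framed) {
  w <- unique(nchar(framed))
  if (length(w) != 1) stop("framed strings must share one width",
                           call. = FALSE)
  chars <- strsplit(framed, "")
  idx <- token_index()
  m <- matrix(idx[unlist(chars, use.names = FALSE)],
              nrow = length(framed), ncol = w, byrow = TRUE)
  if (anyNA(m)) stop("framed strings contain characters outside the ",
                     "19-token alphabet", call. = FALSE)
  m
}

#' One-hot encode a framed sequence
#'
#' Explicit binary representation: one row per position, one column per
#' token, a single 1 per row. Flattening is position-major (row 1 first), so
#' a width-18 frame flattens to length 342 and a width-13 frame to 247.
#'
#' @param framed A single framed string.
#' @param flatten Return the flattened vector instead of the matrix.
#' @return Binary matrix (width x 19) or vector (width * 19).
#' @export
one_hot <- function(framed, flatten = FALSE) {
  stopifnot(length(framed) == 1)
  tok <- encode_tokens(framed)[1, ]
  m <- matrix(0L, length(tok), 19L,
              dimnames = list(NULL, token_alphabet()))
  m[cbind(seq_along(tok), tok)] <- 1L
  if (flatten) as.integer(t(m)) else m
}

#' Decode a one-hot matrix back to its framed string
#'
#' @param m Binary matrix as produced by [one_hot()].
#' @return The framed string.
#' @export
decode_one_hot <- function(m) {
  stopifnot(all(rowSums(m) == 1))
  paste(token_alphabet()[max.col(m)], collapse = "")
}
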