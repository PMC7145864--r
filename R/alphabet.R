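#' Residue alphabets with modification characters
#'
#' An alphabet maps every residue symbol the model can see to a column of the
#' one-hot encoding.  The 20 canonical amino acids are always present; each
#' *variable* modification is registered as an extra single-character token so
#' modified peptides can be encoded alongside unmodified ones.  Fixed,
#' experiment-wide modifications (carbamidomethyl C, TMT/iTRAQ labels) apply
#' to every occurrence of a residue and therefore carry no sequence
#' information: they are not given separate characters.
#'
#' @param modifications named character vector; names are `"<residue>[<mod>]"`
#'   (e.g. `"M[ox]"`), values are the single replacement characters.  The
#'   default registers oxidized methionine as `"1"`.
#' @return an object of class `rt_alphabet` with elements `tokens` (ordered
#'   character vector: canonical residues then modification characters),
#'   `mods` (the modification table) and `base` (modification character ->
#'   base residue map).
#' @examples
#' ab <- rt_alphabet()
#' length(ab$tokens)  # 21
#' @export
rt_alphabet <- function(modifications = c("M[ox]" = "1")) {
  canonical <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  mods <- modifications
  if (length(mods)) {
    if (is.null(names(mods)) || any(!nzchar(names(mods))))
      stop("modifications must be a named character vector", call. = FALSE)
    bad <- !grepl("^[A-Z]\\[[^][]+\\]$", names(mods))
    if (any(bad))
      stop("malformed modification name(s): ",
           paste(names(mods)[bad], collapse = ", "),
           " (expected \"<residue>[<mod>]\")", call. = FALSE)
    if (any(nchar(mods) != 1L))
      stop("modification characters must be single characters", call. = FALSE)
    clash <- mods[mods %in% canonical]
    if (length(clash))
      stop("modification character collides with a canonical residue: ",
           paste(names(clash), "-> ", clash, collapse = ", "), call. = FALSE)
    if (anyDuplicated(mods))
      stop("duplicate modification character: ",
           paste(mods[duplicated(mods)], collapse = ", "), call. = FALSE)
  }
  tokens <- c(canonical, unname(mods))
  base <- substr(names(mods), 1L, 1L)
  names(base) <- unname(mods)
  structure(list(tokens = tokens, mods = mods, base = base),
            class = "rt_alphabet")
}

#' @export
print.rt_alphabet <- function(x, ...) {
  cat("Residue alphabet:", length(x$tokens), "tokens\n")
  cat("  canonical: ", paste(x$tokens[1:20], collapse = ""), "\n", sep = "")
  if (length(x$mods))
    cat("  modifications: ",
        paste(names(x$mods), "->", unname(x$mods), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

alphabet_index <- function(alphabet) {
  setNames(seq_along(alphabet$tokens), alphabet$tokens)
}

#' Tokenize peptides written in bracket notation
#'
#' Converts strings such as `"PEPM[ox]K"` into token strings over the
#' alphabet, replacing each registered modified residue with its modification
#' character (`"PEP1K"` with the default alphabet).  Unknown residues
#' (including B, J, O, U, X, Z) and unregistered modifications are rejected
#' with the offending position; silent imputation would corrupt the RT
#' features downstream.
#'
#' @param x character vector of peptide strings in bracket notation.
#' @param alphabet an [rt_alphabet()].
#' @return character vector of token strings, same length as `x`.
#' @examples
#' pep_tokenize("PEPM[ox]K", rt_alphabet())  # "PEP1K"
#' @export
pep_tokenize <- function(x, alphabet = rt_alphabet()) {
  idx <- alphabet_index(alphabet)
  canonical <- alphabet$tokens[1:20]
  vapply(x, function(raw) {
    chars <- strsplit(raw, "", fixed = TRUE)[[1]]
    out <- character(0)
    i <- 1L
    n <- length(chars)
    while (i <= n) {
      ch <- chars[i]
      if (!ch %in% canonical)
        stop("unknown residue '", ch, "' at position ", i, " in '", raw, "'",
             call. = FALSE)
      if (i < n && chars[i + 1L] == "[") {
        close <- i + 1L
        while (close <= n && chars[close] != "]") close <- close + 1L
        if (close > n)
          stop("unterminated modification bracket at position ", i + 1L,
               " in '", raw, "'", call. = FALSE)
        modname <- paste(chars[(i + 2L):(close - 1L)], collapse = "")
        key <- paste0(ch, "[", modname, "]")
        if (!key %in% names(alphabet$mods))
          stop("unregistered modification '", key, "' at position ", i,
               " in '", raw, "'", call. = FALSE)
        out <- c(out, unname(alphabet$mods[key]))
        i <- close + 1L
      } else {
        out <- c(out, ch)
        i <- i + 1L
      }
    }
    if (!length(out))
      stop("empty peptide string", call. = FALSE)
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Recover the unmodified sequence from a token string
#'
#' Maps each modification character back to its base residue, e.g. `"PEP1K"`
#' to `"PEPMK"` under the default alphabet.
#'
#' @inheritParams pep_tokenize
#' @param tokens character vector of token strings.
#' @return character vector of plain sequences.
#' @export
pep_plain <- function(tokens, alphabet = rt_alphabet()) {
  if (!length(alphabet$base)) return(tokens)
  for (mc in names(alphabet$base))
    tokens <- gsub(mc, alphabet$base[[mc]], tokens, fixed = TRUE)
  tokens
}

#' One-hot encode a token string
#'
#' Encodes a peptide as a `fixed_length` x `|alphabet|` binary matrix: row
#' *i* is the one-hot vector of token *i*, and positions beyond the peptide
#' are zero rows (post-padding).  The fixed length is conventionally the
#' longest peptide in the training corpus.
#'
#' @param tokens a single token string (as produced by [pep_tokenize()]).
#' @param alphabet an [rt_alphabet()].
#' @param fixed_length number of rows of the encoding; must be at least the
#'   peptide length.
#' @return a binary matrix with `fixed_length` rows, one column per alphabet
#'   token (in alphabet order).
#' @examples
#' m <- pep_encode_onehot("ACD", rt_alphabet(), fixed_length = 5)
#' sum(m)  # 3
#' @export
pep_encode_onehot <- function(tokens, alphabet, fixed_length) {
  stopifnot(length(tokens) == 1L)
  ids <- token_ids(tokens, alphabet)
  if (length(ids) > fixed_length)
    stop("peptide length ", length(ids), " exceeds fixed_length ",
         fixed_length, call. = FALSE)
  m <- matrix(0L, nrow = fixed_length, ncol = length(alphabet$tokens),
              dimnames = list(NULL, alphabet$tokens))
  if (length(ids))
    m[cbind(seq_along(ids), ids)] <- 1L
  m
}

#' Decode a one-hot matrix back to its token string
#'
#' Inverse of [pep_encode_onehot()]: non-zero rows are mapped back to tokens
#' via the position of their single 1; all-zero (padding) rows terminate the
#' peptide.
#'
#' @param m a binary matrix as produced by [pep_encode_onehot()].
#' @param alphabet the alphabet used for encoding.
#' @return the token string.
#' @export
pep_decode <- function(m, alphabet) {
  occupied <- rowSums(m) > 0
  if (!any(occupied)) return("")
  last <- max(which(occupied))
  ids <- max.col(m[seq_len(last), , drop = FALSE], ties.method = "first")
  paste(alphabet$tokens[ids], collapse = "")
}

# Integer token indices (1-based; the packed encoding the network core
# consumes - one-hot is materialized inside the C++ forward pass).
token_ids <- function(tokens, alphabet) {
  idx <- alphabet_index(alphabet)
  chars <- strsplit(tokens, "", fixed = TRUE)[[1]]
  unknown <- !chars %in% names(idx)
  if (any(unknown))
    stop("token '", chars[which(unknown)[1]], "' at position ",
         which(unknown)[1], " not in alphabet", call. = FALSE)
  unname(idx[chars])
}

# n x fixed_length integer matrix, 0 = padding. Used by rtnet().
pep_encode_index <- function(tokens, alphabet, fixed_length) {
  n <- length(tokens)
  m <- matrix(0L, nrow = n, ncol = fixed_length)
  for (i in seq_len(n)) {
    ids <- token_ids(tokens[i], alphabet)
    if (length(ids) > fixed_length)
      stop("peptide ", i, " has length ", length(ids),
           " > fixed_length ", fixed_length, call. = FALSE)
    if (length(ids)) m[i, seq_along(ids)] <- ids
  }
  m
}
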