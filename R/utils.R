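# internal helpers shared across modules

stopf <- function(fmt, ..., class = "seqtileqc_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

warnf <- function(fmt, ...) rlang::warn(sprintf(fmt, ...))

# decode a Phred+33 quality string to integer scores
phred_decode <- function(q) utf8ToInt(q) - 33L

# encode integer scores to a Phred+33 string
phred_encode <- function(v) intToUtf8(v + 33L)

# build an [n x L] character matrix from equal-or-ragged-length strings,
# padding short rows with NA
string_matrix <- function(x, width = NULL) {
  sp <- strsplit(x, NULL)
  lens <- lengths(sp)
  L <- width %||% if (length(lens)) max(lens) else 0L
  if (L == 0L) return(matrix(character(), nrow = length(x), ncol = 0L))
  if (all(lens == L)) {
    matrix(unlist(sp, use.names = FALSE), nrow = length(x), ncol = L, byrow = TRUE)
  } else {
    m <- matrix(NA_character_, nrow = length(x), ncol = L)
    for (i in seq_along(sp)) if (lens[i] > 0L) m[i, seq_len(lens[i])] <- sp[[i]]
    m
  }
}

# decode quality strings into an [n x L] integer matrix (NA-padded)
qual_matrix <- function(quals, width = NULL) {
  n <- length(quals)
  lens <- nchar(quals)
  L <- width %||% if (n) max(lens) else 0L
  if (L == 0L) return(matrix(integer(), nrow = n, ncol = 0L))
  if (all(lens == L)) {
    codes <- utf8ToInt(paste(quals, collapse = "")) - 33L
    matrix(codes, nrow = n, ncol = L, byrow = TRUE)
  } else {
    m <- matrix(NA_integer_, nrow = n, ncol = L)
    for (i in seq_len(n)) if (lens[i] > 0L) m[i, seq_len(lens[i])] <- phred_decode(quals[i])
    m
  }
}

# paste the columns of a character matrix row-wise into strings
collapse_rows <- function(m) {
  if (ncol(m) == 0L) return(character(nrow(m)))
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}
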