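# 2048-bit circular (Morgan/ECFP, radius 2) fingerprints via OpenBabel's
# ECFP4 implementation, folded to 2048 bits by obabel itself (-xN2048).
# One obabel process per batch; the hex dump is parsed here.

.hex_bits <- local({
  tab <- matrix(0L, nrow = 16, ncol = 4)
  for (v in 0:15) tab[v + 1L, ] <- as.integer(intToBits(v)[4:1])
  rownames(tab) <- c(0:9, letters[1:6])
  tab
})

hex_to_bits <- function(hex) {
  chars <- strsplit(tolower(hex), "", fixed = TRUE)[[1]]
  as.integer(t(.hex_bits[chars, , drop = FALSE]))
}

#' Morgan fingerprints for a set of molecules
#'
#' Computes a binary 2048-bit circular substructure fingerprint (radius 2,
#' ECFP4 identifiers folded to 2048 bits) for each SMILES. Deterministic for
#' a given canonical SMILES.
#'
#' @param smiles character vector of SMILES strings.
#' @param nbits number of bits after folding (default 2048).
#' @return integer matrix with one row per input and `nbits` columns of 0/1;
#'   rows of `NA` where the molecule could not be parsed.
#' @export
morgan_fingerprint <- function(smiles, nbits = 2048L) {
  stopifnot(is.character(smiles), nbits >= 32L, nbits %% 32L == 0L)
  out <- matrix(NA_integer_, nrow = length(smiles), ncol = nbits)
  ok <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  idx <- which(ok)
  if (length(idx) == 0L) return(out)
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".fpt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(paste(smiles[idx], idx), infile)
  suppressWarnings(system2(
    ob_binary(),
    c(infile, "-ofpt", "-O", outfile, "-xfECFP4",
      paste0("-xN", nbits), "-xh"),
    stdout = FALSE, stderr = FALSE))
  if (!file.exists(outfile)) return(out)
  lines <- readLines(outfile, warn = FALSE)
  cur <- NA_integer_
  buf <- character(0)
  flush_mol <- function(key, hexwords) {
    if (is.na(key) || length(hexwords) == 0L) return()
    bits <- hex_to_bits(paste(hexwords, collapse = ""))
    if (length(bits) == nbits) out[key, ] <<- bits
  }
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      flush_mol(cur, buf)
      buf <- character(0)
      key <- sub("^>([0-9]+).*$", "\\1", ln)
      cur <- suppressWarnings(as.integer(key))
      if (!is.na(cur) && (cur < 1L || cur > length(smiles))) cur <- NA_integer_
    } else {
      tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      buf <- c(buf, tok[grepl("^[0-9a-fA-F]{8}$", tok)])
    }
  }
  flush_mol(cur, buf)
  out
}

# Tanimoto similarity between two 0/1 bit vectors.
tanimoto <- function(a, b) {
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(0)
  inter / uni
}
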