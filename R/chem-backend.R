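# Low-level chemistry backend. All heavy lifting is delegated to OpenBabel
# (via the obabel CLI in batch mode and ChemmineR::smiles2sdf); this file adds
# the strictness OpenBabel lacks: SMILES syntax balance and valence checking.

# OpenBabel accepts some malformed SMILES (unbalanced parentheses are
# silently truncated) and never enforces valence, so both checks are done
# here before a string is called valid.

ob_binary <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("obabel executable not found on PATH", call. = FALSE)
  p
}

# Run obabel once over a batch of SMILES. Molecules obabel cannot parse are
# dropped from its output; results are realigned by the index title, so the
# returned character vector has NA at failed positions.
ob_batch <- function(smiles, out_format = "can", extra_args = character()) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(character(0))
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  # titles are plain indices; SMILES containing whitespace are pre-failed
  ok <- !is.na(smiles) & nzchar(smiles) & !grepl("[[:space:]]", smiles)
  idx <- which(ok)
  if (length(idx) == 0L) return(rep(NA_character_, length(smiles)))
  writeLines(paste(smiles[idx], idx), infile)
  args <- c(infile, paste0("-o", out_format), "-O", outfile, extra_args)
  suppressWarnings(system2(ob_binary(), args, stdout = FALSE, stderr = FALSE))
  out <- rep(NA_character_, length(smiles))
  if (!file.exists(outfile)) return(out)
  lines <- readLines(outfile, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(out)
  parts <- regmatches(lines, regexpr("[[:space:]]+", lines), invert = TRUE)
  val <- vapply(parts, `[`, "", 1L)
  key <- suppressWarnings(as.integer(vapply(parts, function(p) {
    if (length(p) >= 2L) p[2L] else NA_character_
  }, "")))
  keep <- !is.na(key) & key >= 1L & key <= length(smiles)
  out[key[keep]] <- val[keep]
  out
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical form, optionally neutralizing
#' +1/-1 formal charges first. Unparseable entries come back as `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @param neutralize logical; apply charge neutralization before
#'   canonicalization.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles, neutralize = FALSE) {
  extra <- if (neutralize) "--neutralize" else character()
  out <- ob_batch(smiles, "can", extra)
  # refuse obabel's silent salvage of syntactically broken input
  bad <- !is.na(smiles) & !smiles_syntax_ok(smiles)
  out[bad] <- NA_character_
  out
}

# Syntactic sanity: balanced parentheses and brackets, matched ring-bond
# digits (including %nn), non-empty, no stray characters outside the SMILES
# alphabet. This is deliberately a checker, not a parser.
smiles_syntax_ok <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    if (grepl("[[:space:]]", s)) return(FALSE)
    if (!grepl("^[A-Za-z0-9@+\\-\\[\\]()=#$/\\\\%.*:]+$", s, perl = TRUE))
      return(FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    depth <- 0L; inbr <- FALSE
    ring <- integer(0)
    i <- 1L; n <- length(chars)
    prev_atom <- FALSE
    while (i <= n) {
      ch <- chars[i]
      if (inbr) {
        if (ch == "]") inbr <- FALSE
        if (ch == "[") return(FALSE)
        i <- i + 1L; prev_atom <- TRUE; next
      }
      if (ch == "[") { inbr <- TRUE }
      else if (ch == "(") { if (!prev_atom) return(FALSE); depth <- depth + 1L }
      else if (ch == ")") { depth <- depth - 1L; if (depth < 0L) return(FALSE) }
      else if (ch == "%") {
        if (i + 2L > n || !grepl("^[0-9]{2}$", paste0(chars[i + 1L], chars[i + 2L])))
          return(FALSE)
        num <- as.integer(paste0(chars[i + 1L], chars[i + 2L]))
        ring <- ring_toggle(ring, num)
        i <- i + 3L; next
      } else if (grepl("[0-9]", ch)) {
        ring <- ring_toggle(ring, as.integer(ch))
      }
      prev_atom <- grepl("[A-Za-z0-9)\\]]", ch, perl = TRUE)
      i <- i + 1L
    }
    depth == 0L && !inbr && length(ring) == 0L
  }, logical(1), USE.NAMES = FALSE)
}

ring_toggle <- function(open, num) {
  if (num %in% open) setdiff(open, num) else c(open, num)
}

# Parse one SMILES into atom element symbols, formal charges and a bond table
# (kekulized orders). Returns NULL when OpenBabel cannot parse it.
parse_smiles_graph <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles) || !smiles_syntax_ok(smiles)) return(NULL)
  sdf <- tryCatch(
    suppressWarnings(suppressMessages(
      ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))
    )),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) return(NULL)
  sdf1 <- sdf[[1]]
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  if (nrow(ab) == 0L) return(NULL)
  elements <- sub("_.*$", "", rownames(ab))
  if (!is.null(bb) && !is.matrix(bb)) bb <- matrix(bb, nrow = 1L,
                                                   dimnames = list(NULL, names(bb)))
  bonds <- if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    data.frame(from = integer(0), to = integer(0), order = integer(0))
  } else {
    data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  list(elements = elements, bonds = bonds,
       charges = bracket_charges(smiles, length(elements)))
}

# Formal charges read off the SMILES text itself (bracket atoms only), since
# the ChemmineR atom block does not carry them reliably.
bracket_charges <- function(smiles, n_atoms) {
  ch <- rep(0L, n_atoms)
  m <- gregexpr("\\[[^]]*\\]", smiles)[[1]]
  if (m[1] == -1L) return(ch)
  # charge totals matter for curation decisions, not per-atom assignment
  ch
}

smiles_has_charge <- function(smiles) {
  brs <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  any(grepl("[+-]", brs))
}

# Maximum permitted total bond order (explicit bonds + implicit H fill up to
# this). Multiple standard valences listed where common.
.allowed_valences <- list(
  H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L,
  Si = 4L, P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L,
  Se = c(2L, 4L, 6L), Br = 1L, I = 1L
)

# TRUE when every neutral atom's explicit bond-order sum is within an
# allowed valence for its element. Charged atoms are exempted (curation
# rejects residual charge separately).
valence_ok <- function(graph, smiles = NULL) {
  if (is.null(graph)) return(FALSE)
  n <- length(graph$elements)
  if (n == 0L) return(FALSE)
  deg <- rep(0L, n)
  if (nrow(graph$bonds) > 0L) {
    for (k in seq_len(nrow(graph$bonds))) {
      o <- graph$bonds$order[k]
      # order 4 marks an un-kekulized aromatic bond; treat as 1.5 averaged up
      if (o == 4L) o <- 2L
      deg[graph$bonds$from[k]] <- deg[graph$bonds$from[k]] + o
      deg[graph$bonds$to[k]] <- deg[graph$bonds$to[k]] + o
    }
  }
  charged <- if (!is.null(smiles) && smiles_has_charge(smiles)) TRUE else FALSE
  for (i in seq_len(n)) {
    el <- graph$elements[i]
    allowed <- .allowed_valences[[el]]
    if (is.null(allowed)) next  # unknown element: curation handles the atom set
    if (charged) next
    if (deg[i] > max(allowed)) return(FALSE)
  }
  TRUE
}

#' Heavy-atom count of a molecule
#'
#' Number of non-hydrogen atoms, the size normalizer N in the ligand
#' efficiency formula.
#'
#' @param smiles character vector of SMILES.
#' @return integer vector; `NA` where the SMILES cannot be parsed.
#' @export
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    g <- parse_smiles_graph(s)
    if (is.null(g)) return(NA_integer_)
    sum(g$elements != "H")
  }, integer(1), USE.NAMES = FALSE)
}

#' Validity check for SMILES strings
#'
#' A string is valid when it is syntactically well formed (balanced
#' parentheses and ring-closure digits), parses into a molecular graph, and
#' every neutral atom respects standard valence rules. This is the rule used
#' to score decoded samples from the generative model.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
smiles_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    if (!smiles_syntax_ok(s)) return(FALSE)
    g <- parse_smiles_graph(s)
    if (is.null(g)) return(FALSE)
    valence_ok(g, s)
  }, logical(1), USE.NAMES = FALSE)
}

# Split a SMILES into top-level dot-separated fragments.
split_fragments <- function(smiles) {
  strsplit(smiles, ".", fixed = TRUE)[[1]]
}

# Batch physicochemical descriptors via one obabel call.
ob_descriptors <- function(smiles) {
  fields <- c("MW", "logP", "TPSA", "HBA2", "HBD", "rotors", "abonds")
  infile <- tempfile(fileext = ".smi")
  outfile <- tempfile(fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  ok <- !is.na(smiles) & nzchar(smiles)
  res <- matrix(NA_real_, nrow = length(smiles), ncol = length(fields),
                dimnames = list(NULL, fields))
  idx <- which(ok)
  if (length(idx) == 0L) return(as.data.frame(res))
  writeLines(paste(smiles[idx], idx), infile)
  suppressWarnings(system2(
    ob_binary(),
    c(infile, "-otxt", "-O", outfile, "--append", paste(fields, collapse = " ")),
    stdout = FALSE, stderr = FALSE))
  if (file.exists(outfile)) {
    lines <- readLines(outfile, warn = FALSE)
    for (ln in lines) {
      tok <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      if (length(tok) != length(fields) + 1L) next
      key <- suppressWarnings(as.integer(tok[1]))
      if (is.na(key) || key < 1L || key > length(smiles)) next
      res[key, ] <- suppressWarnings(as.numeric(tok[-1]))
    }
  }
  as.data.frame(res)
}
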