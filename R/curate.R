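# Corpus curation following the standard ChEMBL preparation rules:
# salt stripping (keep the largest fragment), charge neutralization,
# removal of SMILES longer than 100 characters, and restriction to a fixed
# element set.

#' Default element set for curation
#'
#' @return character vector of allowed element symbols.
#' @export
default_allowed_atoms <- function() {
  c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Se", "Br", "I")
}

.reason_levels <- c("unparseable", "too_long", "disallowed_atom")

# Elements present in a SMILES string, from its graph (so aromatic lowercase
# and bracket atoms are resolved properly).
smiles_elements <- function(smiles) {
  g <- parse_smiles_graph(smiles)
  if (is.null(g)) return(NULL)
  unique(g$elements)
}

#' Curate a single compound record
#'
#' Applies the corpus preparation rules: the input must be syntactically
#' valid and parseable; the largest fragment (by heavy atoms, ties broken by
#' lexicographically smallest canonical SMILES) is kept; +1/-1 formal
#' charges are neutralized; strings longer than `max_len` characters (before
#' or after canonicalization) are rejected; molecules containing elements
#' outside `allowed_atoms` are rejected. Never throws on bad input.
#'
#' @param raw_smiles a single SMILES string as read from input.
#' @param allowed_atoms permitted element symbols.
#' @param max_len maximum SMILES length (default 100).
#' @return on success, a list of class `curated_molecule` with elements
#'   `smiles` (canonical), `heavy_atom_count` and `length`; on failure a
#'   list of class `curation_rejection` with elements `reason` (one of
#'   `unparseable`, `too_long`, `disallowed_atom`) and `detail`.
#' @examples
#' \dontrun{
#' curate_record("CCO.Cl")          # keeps the ethanol fragment
#' curate_record("[AsH3]")          # rejected: disallowed_atom
#' }
#' @export
curate_record <- function(raw_smiles,
                          allowed_atoms = default_allowed_atoms(),
                          max_len = 100L) {
  if (!is.character(raw_smiles) || length(raw_smiles) != 1L ||
      is.na(raw_smiles) || !nzchar(raw_smiles)) {
    return(structure(list(reason = "unparseable",
                          detail = "empty or non-character input"),
                     class = "curation_rejection"))
  }
  row <- curate_corpus(raw_smiles, allowed_atoms = allowed_atoms,
                       max_len = max_len)
  if (row$accepted[1]) {
    structure(list(smiles = row$smiles[1],
                   heavy_atom_count = row$heavy_atoms[1],
                   length = nchar(row$smiles[1])),
              class = "curated_molecule")
  } else {
    structure(list(reason = row$reason[1], detail = row$detail[1]),
              class = "curation_rejection")
  }
}

#' @export
print.curated_molecule <- function(x, ...) {
  cat("<curated molecule>", x$smiles,
      sprintf("(%d heavy atoms)\n", x$heavy_atom_count))
  invisible(x)
}

#' Curate a corpus of SMILES strings
#'
#' Vectorized [curate_record()]. Returns one row per input with the curation
#' outcome; accepted rows carry the canonical SMILES and heavy-atom count,
#' rejected rows the rejection reason.
#'
#' @param smiles character vector of raw SMILES.
#' @param ids optional identifiers (defaults to the input index).
#' @inheritParams curate_record
#' @return data.frame with columns `source_id`, `raw_smiles`, `accepted`,
#'   `smiles`, `heavy_atoms`, `reason`.
#' @export
curate_corpus <- function(smiles, ids = NULL,
                          allowed_atoms = default_allowed_atoms(),
                          max_len = 100L) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  reason <- rep(NA_character_, n)
  detail <- rep("", n)
  out_smiles <- rep(NA_character_, n)
  out_heavy <- rep(NA_integer_, n)

  bad_input <- is.na(smiles) | !nzchar(smiles)
  reason[bad_input] <- "unparseable"
  detail[bad_input] <- "empty input"
  too_long <- !bad_input & nchar(smiles) > max_len
  reason[too_long] <- "too_long"
  detail[too_long] <- sprintf("%d characters", nchar(smiles)[too_long])
  open <- is.na(reason)
  bad_syn <- open & !smiles_syntax_ok(ifelse(is.na(smiles), "", smiles))
  reason[bad_syn] <- "unparseable"
  detail[bad_syn] <- "malformed SMILES syntax"
  open <- is.na(reason)

  # salt strip: keep the fragment with the most heavy atoms; ties broken by
  # lexicographically smallest canonical SMILES
  frag <- smiles
  for (i in which(open & grepl(".", smiles, fixed = TRUE))) {
    fr <- split_fragments(smiles[i])
    counts <- heavy_atom_count(fr)
    if (all(is.na(counts))) {
      reason[i] <- "unparseable"; detail[i] <- "no parseable fragment"
      next
    }
    counts[is.na(counts)] <- -1L
    best <- which(counts == max(counts))
    if (length(best) > 1L) {
      cands <- canonical_smiles(fr[best])
      cands[is.na(cands)] <- "~"   # sorts last
      best <- best[order(cands, method = "radix")[1L]]
    }
    frag[i] <- fr[best]
  }
  open <- is.na(reason)

  can <- rep(NA_character_, n)
  if (any(open)) {
    can[open] <- canonical_smiles(frag[open], neutralize = TRUE)
  }
  failed <- open & is.na(can)
  reason[failed] <- "unparseable"
  detail[failed] <- "OpenBabel could not parse"
  open <- is.na(reason)

  for (i in which(open)) {
    ci <- can[i]
    if (smiles_has_charge(ci)) {
      reason[i] <- "disallowed_atom"
      detail[i] <- "residual formal charge after neutralization"
      next
    }
    g <- parse_smiles_graph(ci)
    if (is.null(g)) {
      reason[i] <- "unparseable"; detail[i] <- "canonical form unparseable"
      next
    }
    if (!valence_ok(g, ci)) {
      reason[i] <- "unparseable"; detail[i] <- "valence violation"
      next
    }
    bad <- setdiff(unique(g$elements), allowed_atoms)
    if (length(bad) > 0L) {
      reason[i] <- "disallowed_atom"; detail[i] <- paste(bad, collapse = ",")
      next
    }
    if (nchar(ci) > max_len) {
      reason[i] <- "too_long"
      detail[i] <- sprintf("canonical form %d characters", nchar(ci))
      next
    }
    out_smiles[i] <- ci
    out_heavy[i] <- sum(g$elements != "H")
  }

  data.frame(
    source_id = ids,
    raw_smiles = smiles,
    accepted = is.na(reason),
    smiles = out_smiles,
    heavy_atoms = out_heavy,
    reason = reason,
    detail = detail,
    stringsAsFactors = FALSE
  )
}

#' Read SMILES input
#'
#' Reads `.smi` (whitespace-separated SMILES plus optional identifier) or
#' plain one-SMILES-per-line text.
#'
#' @param path file path.
#' @return data.frame with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  data.frame(
    smiles = vapply(parts, `[`, "", 1L),
    id = vapply(seq_along(parts), function(i) {
      p <- parts[[i]]
      if (length(p) >= 2L) paste(p[-1L], collapse = " ") else as.character(i)
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Write SMILES output
#'
#' @param smiles character vector.
#' @param path destination file.
#' @param ids optional identifiers appended after each SMILES.
#' @export
write_smi <- function(smiles, path, ids = NULL) {
  lines <- if (is.null(ids)) smiles else paste(smiles, ids)
  writeLines(lines, path)
  invisible(path)
}

#' Deterministic train/validation split
#'
#' Splits curated molecules into train and validation sets by hashing the
#' canonical SMILES together with a seed, so membership is reproducible and
#' independent of input order.
#'
#' @param smiles character vector of canonical SMILES.
#' @param val_fraction fraction assigned to the validation set.
#' @param seed integer seed entering the hash.
#' @return character vector `"train"`/`"val"`, one element per input.
#' @export
split_corpus <- function(smiles, val_fraction = 0.15, seed = 1L) {
  stopifnot(val_fraction >= 0, val_fraction < 1)
  h <- vapply(smiles, function(s) {
    x <- utf8ToInt(paste0(s, ":", seed))
    sum(x * (seq_along(x) %% 97 + 1)) %% 10000L
  }, 1, USE.NAMES = FALSE)
  ifelse(h < val_fraction * 10000, "val", "train")
}
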