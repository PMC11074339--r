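# Synthetic fixture corpora: small families of structurally related, valid
# molecules standing in for a real training corpus. Each family shares a
# distinctive scaffold; members differ by an enumerated aliphatic/ether/amine
# substituent, so families are separable by fingerprint similarity while the
# whole corpus stays in easy C/N/O chemistry.

# Scaffolds are written so that prefixing a substituent chain (which always
# ends in an atom) yields a valid SMILES: each begins with an attachable atom.
.fixture_scaffolds <- c(
  "C1CCN(CC1)C(C)=O",        # N-acyl piperidine
  "c1ccc2c(c1)OCO2",         # benzodioxole
  "C1COCCN1C=O",             # N-formyl morpholine
  "c1ccncc1",                # pyridine
  "C1CCOC1CO",               # tetrahydrofurfuryl alcohol
  "c1ccc(cc1)OC",            # anisole
  "C1CCCCC1O",               # cyclohexanol
  "N(C)C(=O)c1ccccc1",       # N-methyl benzamide
  "OCC(O)CO",                # glycerol backbone
  "c1ccc(cc1)C#N",           # benzonitrile
  "C1CC1C(=O)OC",            # cyclopropane ester
  "N1C=CC=C1C=O"             # pyrrole carbaldehyde
)

# Substituent chains over {C, N, O}: start with carbon, no adjacent
# heteroatoms, at most two heteroatoms. Enumerated deterministically.
fixture_substituents <- function(max_len = 5L) {
  pool <- "C"
  grow <- function(prefixes) {
    out <- character(0)
    for (p in prefixes) {
      last <- substr(p, nchar(p), nchar(p))
      for (a in c("C", "N", "O")) {
        if (a != "C" && last != "C") next
        cand <- paste0(p, a)
        n_het <- nchar(gsub("C", "", cand))
        if (n_het <= 2L) out <- c(out, cand)
      }
    }
    out
  }
  all <- pool
  cur <- pool
  for (len in 2:max_len) {
    cur <- grow(cur)
    all <- c(all, cur)
  }
  # terminal N/O only (a chain ending in N/O is a plain amine/alcohol/ether)
  all
}

#' Generate a synthetic fixture corpus
#'
#' Builds `n_families` structural families of `family_size` molecules each.
#' Every family is one scaffold decorated with distinct substituent chains;
#' all members pass [curate_record()] unchanged, and fingerprint similarity
#' within a family exceeds similarity across families.
#'
#' @param n_families number of families (1 to 12).
#' @param family_size molecules per family.
#' @param seed integer seed; the same call always returns the same corpus.
#' @return data.frame with columns `smiles` (canonical), `family`,
#'   `heavy_atoms`.
#' @export
generate_fixture_corpus <- function(n_families, family_size, seed = 1L) {
  stopifnot(n_families >= 1L, family_size >= 1L)
  if (n_families > length(.fixture_scaffolds)) {
    stop(sprintf("at most %d families are available",
                 length(.fixture_scaffolds)))
  }
  subs <- fixture_substituents()
  if (family_size > length(subs)) {
    stop(sprintf("family_size of at most %d is supported", length(subs)))
  }
  rng <- local({
    set.seed(as.integer(seed) %% .Machine$integer.max)
    function(n, k) sample.int(n, k)
  })
  rows <- list()
  for (f in seq_len(n_families)) {
    scaffold <- .fixture_scaffolds[f]
    chosen <- subs[rng(length(subs), family_size)]
    raw <- paste0(chosen, scaffold)
    cur <- curate_corpus(raw)
    if (!all(cur$accepted)) {
      stop(sprintf("internal fixture defect: family %d produced %d invalid members",
                   f, sum(!cur$accepted)))
    }
    rows[[f]] <- data.frame(smiles = cur$smiles, family = f,
                            heavy_atoms = cur$heavy_atoms,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hand-built curation defect fixture
#'
#' Twenty raw records with known defects: 13 clean molecules, 2 salts whose
#' parent passes after stripping, 3 SMILES over 100 characters and 2 with a
#' disallowed element. Used to exercise the full curation contract.
#'
#' @return data.frame with columns `raw_smiles` and `defect` (one of
#'   `clean`, `salt`, `too_long`, `disallowed_atom`).
#' @export
curation_defect_fixture <- function() {
  clean <- c(
    "CCO", "CC(=O)O", "c1ccccc1", "CCN(CC)CC", "C1CCOC1",
    "CC(C)CO", "c1ccncc1", "COC(=O)c1ccccc1", "CC(=O)Nc1ccccc1",
    "OCC(O)CO", "C1CCCCC1", "CCOC(C)=O", "CN1CCCC1"
  )
  salts <- c("CCO.Cl", "CC(=O)[O-].[Na+]")
  too_long <- c(
    strrep("C", 101L),
    paste0(strrep("CC(C)", 25L), "CO"),          # 127 characters
    paste0("c1ccccc1", strrep("OCC", 40L))       # 128 characters
  )
  disallowed <- c("[AsH3]", "CC[Hg]CC")
  data.frame(
    raw_smiles = c(clean, salts, too_long, disallowed),
    defect = c(rep("clean", length(clean)), rep("salt", length(salts)),
               rep("too_long", length(too_long)),
               rep("disallowed_atom", length(disallowed))),
    stringsAsFactors = FALSE
  )
}
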