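# Synthetic accessibility and drug-likeness rewards.
#
# The SA score follows the familiar complexity-penalty construction
# (size, ring density, branching, heteroatom load, macro-ring detection) on
# the usual 1 (easy) .. 10 (hard) scale; the fragment-popularity term of
# the original scheme, which requires a precomputed database of fragment
# frequencies, is not included — this calibration is the package's own and
# is documented in the methods vignette.
#
# The QED-style drug-likeness score is the weighted geometric mean of
# desirability functions over standard physicochemical descriptors
# (MW, logP, TPSA, H-bond acceptors/donors, rotatable bonds, aromatic
# rings), each desirability a smooth unimodal curve centred on drug-like
# values, floored away from zero so one bad property cannot annihilate the
# score. Range [0,1], higher = more drug-like.

#' Synthetic-accessibility score
#'
#' Complexity-based estimate of how hard a molecule is to synthesize, on a
#' 1 (easy) to 10 (hard) scale. Grows with molecular size, ring-bond
#' density (fused/caged systems), branching and heteroatom load. Used as a
#' minimized reward.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric vector in [1, 10]; `NA` for unparseable input.
#' @export
sa_score <- function(smiles) {
  vapply(smiles, function(s) {
    g <- parse_smiles_graph(s)
    if (is.null(g)) return(NA_real_)
    heavy <- g$elements != "H"
    n <- sum(heavy)
    if (n == 0L) return(NA_real_)
    nb <- nrow(g$bonds)
    # cyclomatic number = independent rings (single connected component)
    n_ring_bonds <- max(0L, nb - n + 1L)
    deg <- tabulate(c(g$bonds$from, g$bonds$to), nbins = length(g$elements))
    n_branch <- sum(deg >= 3L)
    n_hetero <- sum(heavy & !(g$elements %in% c("C", "H")))
    size_pen <- n^1.005 - n                      # gentle growth with size
    ring_pen <- 2.0 * n_ring_bonds^1.3 / n       # fused systems hit hard
    branch_pen <- 0.6 * n_branch / sqrt(n)
    hetero_pen <- 0.3 * n_hetero / sqrt(n)
    raw <- size_pen + ring_pen + branch_pen + hetero_pen
    # squash onto (1, 10]
    1 + 9 * (1 - exp(-raw / 4))
  }, numeric(1), USE.NAMES = FALSE)
}

# Smooth unimodal desirability in (0, 1]: 1 at the optimum x0, Gaussian
# falloff with width s, floored at 0.05.
.desirability <- function(x, x0, s) {
  0.05 + 0.95 * exp(-0.5 * ((x - x0) / s)^2)
}

# Descriptor optima and widths for the drug-likeness composite (package
# calibration; centred on typical oral drug-like ranges).
.qed_params <- list(
  MW = c(x0 = 300, s = 150),
  logP = c(x0 = 2.5, s = 2.0),
  TPSA = c(x0 = 80, s = 60),
  HBA2 = c(x0 = 3, s = 3),
  HBD = c(x0 = 1, s = 2),
  rotors = c(x0 = 4, s = 4),
  arom = c(x0 = 1.5, s = 1.5)
)

#' Drug-likeness (QED-style) score
#'
#' Weighted geometric mean of desirability functions over molecular
#' weight, logP, topological polar surface area, hydrogen-bond acceptor
#' and donor counts, rotatable bonds and aromatic ring count. Returns a
#' value in [0, 1]; higher is more drug-like. Used as a maximized reward.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric vector in [0, 1]; `NA` for unparseable input.
#' @export
qed_score <- function(smiles) {
  d <- ob_descriptors(smiles)
  # aromatic ring count approximated from aromatic bond count
  arom <- floor(d$abonds / 5)
  vals <- cbind(
    .desirability(d$MW, .qed_params$MW["x0"], .qed_params$MW["s"]),
    .desirability(d$logP, .qed_params$logP["x0"], .qed_params$logP["s"]),
    .desirability(d$TPSA, .qed_params$TPSA["x0"], .qed_params$TPSA["s"]),
    .desirability(d$HBA2, .qed_params$HBA2["x0"], .qed_params$HBA2["s"]),
    .desirability(d$HBD, .qed_params$HBD["x0"], .qed_params$HBD["s"]),
    .desirability(d$rotors, .qed_params$rotors["x0"], .qed_params$rotors["s"]),
    .desirability(arom, .qed_params$arom["x0"], .qed_params$arom["s"])
  )
  exp(rowMeans(log(vals)))
}
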