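# The six-reward scoring engine: predicted ligand efficiency against each
# target (r1, r2; maximized), Euclidean distance in the chemical embedding
# to the closest known ligands of each target (r3, r4; minimized), synthetic
# accessibility (r5; minimized) and drug-likeness (r6; maximized). Each raw
# reward is mapped to [0,1] by half-Gaussian scaling and the six normalized
# rewards are averaged into the scalar R.

#' Reward specification
#'
#' One reward's direction and half-Gaussian normalization parameters: on
#' the satisfied side of `mu` the normalized reward is 1; on the
#' unsatisfied side it decays as `exp(-((r - mu)/sigma)^2 / 2)`.
#'
#' @param name one of `le_target1`, `le_target2`, `dist_target1`,
#'   `dist_target2`, `sa`, `qed`.
#' @param direction `"maximize"` or `"minimize"`. Fixed by convention:
#'   ligand efficiency and QED are maximized; embedding distance and SA are
#'   minimized.
#' @param mu threshold mean.
#' @param sigma decay width (> 0).
#' @return object of class `reward_spec`.
#' @export
reward_spec <- function(name, direction = c("maximize", "minimize"),
                        mu, sigma) {
  name <- match.arg(name, c("le_target1", "le_target2", "dist_target1",
                            "dist_target2", "sa", "qed"))
  direction <- match.arg(direction)
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(sigma), sigma > 0)
  structure(list(name = name, direction = direction, mu = mu, sigma = sigma),
            class = "reward_spec")
}

#' Default reward specifications
#'
#' Placeholder thresholds for the six rewards. These are documented
#' placeholders chosen to sit in plausible ranges (ligand efficiency around
#' 0.4, embedding distance a few units, SA mid-scale, QED drug-like); any
#' serious run should set thresholds from its own ligand data via the run
#' configuration.
#'
#' @param le_mu,le_sigma thresholds for both ligand-efficiency rewards.
#' @param dist_mu,dist_sigma thresholds for both embedding-distance rewards.
#' @param sa_mu,sa_sigma threshold for synthetic accessibility.
#' @param qed_mu,qed_sigma threshold for drug-likeness.
#' @return named list of six [reward_spec()] objects.
#' @export
default_reward_specs <- function(le_mu = 0.4, le_sigma = 0.1,
                                 dist_mu = 3, dist_sigma = 1,
                                 sa_mu = 4, sa_sigma = 1,
                                 qed_mu = 0.7, qed_sigma = 0.1) {
  list(
    le_target1 = reward_spec("le_target1", "maximize", le_mu, le_sigma),
    le_target2 = reward_spec("le_target2", "maximize", le_mu, le_sigma),
    dist_target1 = reward_spec("dist_target1", "minimize", dist_mu, dist_sigma),
    dist_target2 = reward_spec("dist_target2", "minimize", dist_mu, dist_sigma),
    sa = reward_spec("sa", "minimize", sa_mu, sa_sigma),
    qed = reward_spec("qed", "maximize", qed_mu, qed_sigma)
  )
}

#' Half-Gaussian reward normalization
#'
#' Maps a raw reward to [0,1]: 1 on the satisfied side of the threshold
#' mean (`r >= mu` when maximizing, `r <= mu` when minimizing), Gaussian
#' falloff `exp(-((r - mu)/sigma)^2 / 2)` on the other side.
#'
#' @param r raw reward values (vectorized).
#' @param spec a [reward_spec()].
#' @return values in [0,1].
#' @export
normalize_half_gaussian <- function(r, spec) {
  stopifnot(inherits(spec, "reward_spec"))
  g <- exp(-0.5 * ((r - spec$mu) / spec$sigma)^2)
  if (spec$direction == "maximize") ifelse(r < spec$mu, g, 1)
  else ifelse(r > spec$mu, g, 1)
}

#' Known-ligand embedding set
#'
#' The latent coordinates (posterior means) of a target's known ligands,
#' embedded with the same VAE checkpoint as the candidates they will be
#' compared against.
#'
#' @param target_id target label.
#' @param embeddings numeric matrix, one row per known ligand.
#' @param k number of closest ligands entering the distance reward
#'   (default 20, capped at the set size).
#' @return object of class `known_ligand_set`.
#' @export
known_ligand_set <- function(target_id, embeddings, k = 20L) {
  stopifnot(is.matrix(embeddings), nrow(embeddings) >= 1L)
  k <- min(as.integer(k), nrow(embeddings))
  structure(list(target_id = target_id, embeddings = embeddings, k = k),
            class = "known_ligand_set")
}

#' Embedding-distance reward
#'
#' Mean Euclidean distance from a candidate's latent coordinate to the `k`
#' closest known ligands of a target (`stat = "mean"`, the default), or the
#' distance to the single nearest of the `k` (`stat = "min"`).
#'
#' @param candidate_mu numeric vector (one candidate's posterior mean) or a
#'   matrix of candidates (rows).
#' @param ligands a [known_ligand_set()].
#' @param stat `"mean"` or `"min"` over the `k` nearest.
#' @return numeric vector of nonnegative distances.
#' @export
distance_reward <- function(candidate_mu, ligands, stat = c("mean", "min")) {
  stat <- match.arg(stat)
  stopifnot(inherits(ligands, "known_ligand_set"))
  if (is.null(dim(candidate_mu))) candidate_mu <- rbind(candidate_mu)
  E <- ligands$embeddings
  if (ncol(candidate_mu) != ncol(E)) stop("latent dimension mismatch")
  k <- ligands$k
  unname(apply(candidate_mu, 1L, function(v) {
    d <- sqrt(colSums((t(E) - v)^2))
    d <- sort(d, method = "radix")[seq_len(k)]
    if (stat == "mean") mean(d) else d[1]
  }))
}

#' Score candidate molecules against the six rewards
#'
#' Computes raw rewards r1..r6 for each candidate (predicted ligand
#' efficiency against the two targets, embedding distance to each target's
#' known ligands, synthetic accessibility, drug-likeness), normalizes each
#' by half-Gaussian scaling, and averages the normalized rewards into R.
#' Candidates for which any component fails (invalid SMILES, featurization
#' failure) are dropped; the number dropped is attached as attribute
#' `n_unscorable`.
#'
#' @param smiles candidate SMILES (need not be pre-curated; invalid ones
#'   are dropped as unscorable).
#' @param model the `smiles_vae` providing the embedding.
#' @param scorers list of two `target_scorer` objects.
#' @param ligand_sets list of two [known_ligand_set()] objects.
#' @param specs named list of six [reward_spec()]s (see
#'   [default_reward_specs()]).
#' @return data.frame: `smiles`, raw `r1`..`r6`, normalized `rn1`..`rn6`,
#'   aggregate `R`.
#' @export
score_candidates <- function(smiles, model, scorers, ligand_sets,
                             specs = default_reward_specs()) {
  stopifnot(length(scorers) == 2L, length(ligand_sets) == 2L,
            length(specs) == 6L)
  need <- c("le_target1", "le_target2", "dist_target1", "dist_target2",
            "sa", "qed")
  if (!all(need %in% names(specs))) {
    stop("specs must be named: ", paste(need, collapse = ", "))
  }
  n_in <- length(smiles)
  ok <- smiles_valid(smiles)
  smiles <- smiles[ok]
  empty <- data.frame(smiles = character(0))
  if (length(smiles) == 0L) {
    attr(empty, "n_unscorable") <- n_in
    return(empty)
  }
  fp_ok <- !apply(is.na(morgan_fingerprint(smiles)), 1L, any)
  desc <- ob_descriptors(smiles)
  desc_ok <- !apply(is.na(desc), 1L, any)
  keep <- fp_ok & desc_ok
  smiles <- smiles[keep]
  if (length(smiles) == 0L) {
    attr(empty, "n_unscorable") <- n_in
    return(empty)
  }
  r1 <- predict_efficiency(scorers[[1]], smiles)
  r2 <- predict_efficiency(scorers[[2]], smiles)
  mu <- vae_encode(model, smiles)$mu
  r3 <- distance_reward(mu, ligand_sets[[1]])
  r4 <- distance_reward(mu, ligand_sets[[2]])
  r5 <- sa_score(smiles)
  r6 <- qed_score(smiles)
  rn <- cbind(
    normalize_half_gaussian(r1, specs$le_target1),
    normalize_half_gaussian(r2, specs$le_target2),
    normalize_half_gaussian(r3, specs$dist_target1),
    normalize_half_gaussian(r4, specs$dist_target2),
    normalize_half_gaussian(r5, specs$sa),
    normalize_half_gaussian(r6, specs$qed)
  )
  out <- data.frame(smiles = smiles, r1 = r1, r2 = r2, r3 = r3, r4 = r4,
                    r5 = r5, r6 = r6,
                    rn1 = rn[, 1], rn2 = rn[, 2], rn3 = rn[, 3],
                    rn4 = rn[, 4], rn5 = rn[, 5], rn6 = rn[, 6],
                    R = rowMeans(rn), stringsAsFactors = FALSE)
  attr(out, "n_unscorable") <- n_in - nrow(out)
  out
}
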