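# Mendelian machinery shared by the brute-force enumerator (the oracle) and
# the peeling engine: Hardy-Weinberg founder priors over {0,1,2} copies of the
# deleterious allele and the autosomal transmission law.

#' Hardy-Weinberg founder prior
#'
#' @param f Deleterious-allele frequency.
#' @return Probabilities of carrying 0, 1, 2 copies: `((1-f)^2, 2f(1-f), f^2)`.
#' @export
hw_prior <- function(f) {
  stopifnot(f >= 0, f <= 1)
  c((1 - f)^2, 2 * f * (1 - f), f^2)
}

#' Mendelian transmission array
#'
#' @param de_novo Per-gamete probability that a transmitted wildtype allele
#'   mutates (default 0).
#' @return A 3 x 3 x 3 array `T[gf+1, gm+1, gc+1] = P(child = gc | gf, gm)`;
#'   every parental row sums to 1.
#' @export
transmission_array <- function(de_novo = 0) {
  p_gamete <- function(g) g / 2 + (1 - g / 2) * de_novo
  arr <- array(0, dim = c(3, 3, 3))
  for (gf in 0:2) for (gm in 0:2) {
    pa <- p_gamete(gf); pb <- p_gamete(gm)
    arr[gf + 1, gm + 1, 1] <- (1 - pa) * (1 - pb)
    arr[gf + 1, gm + 1, 2] <- pa * (1 - pb) + (1 - pa) * pb
    arr[gf + 1, gm + 1, 3] <- pa * pb
  }
  arr
}

clamp_indicator <- function(clamp) {
  # clamp: integer genotype 0/1/2 or "carrier"/"wildtype"
  if (is.numeric(clamp)) {
    v <- c(0, 0, 0); v[clamp + 1] <- 1
  } else if (identical(clamp, "carrier")) {
    v <- c(0, 1, 1)
  } else if (identical(clamp, "wildtype")) {
    v <- c(1, 0, 0)
  } else {
    abort(paste0("unknown clamp: ", clamp))
  }
  v
}

#' Enumerate all Mendelian genotype configurations (brute-force oracle)
#'
#' Exhaustively lists every genotype assignment over a (small) family together
#' with its prior probability: the product of Hardy-Weinberg founder priors and
#' Mendelian transmission probabilities, restricted to the supplied clamps.
#' Over an unclamped pedigree the priors sum to 1; with clamps they sum to the
#' marginal probability of the clamp. Intended as the exactness oracle for the
#' peeling engine, so it refuses pedigrees above `limit` members.
#'
#' @param ped An `lfs_pedigree` holding a single family.
#' @param clamped Named list/vector: id -> genotype (0/1/2) or `"carrier"` /
#'   `"wildtype"`.
#' @param f Allele frequency.
#' @param de_novo De novo rate per gamete.
#' @param limit Refusal limit on family size (default 12).
#' @param drop_zero Drop zero-prior configurations (default `TRUE`).
#' @return A tibble with one genotype column per individual (named by id) and
#'   a `.prior` column.
#' @export
enumerate_genotype_configs <- function(ped, clamped = list(), f = 0.0006,
                                       de_novo = 0, limit = 12,
                                       drop_zero = TRUE) {
  ped <- one_family(as_tibble(ped))
  n <- nrow(ped)
  if (n > limit) {
    abort(paste0("enumeration oracle refused: ", n, " members > limit ", limit))
  }
  ids <- ped$id
  hw <- hw_prior(f)
  tr <- transmission_array(de_novo)
  # configs as an (3^n x n) matrix of genotypes 0:2, column j varying fastest
  m <- 3L^n
  G <- matrix(0L, nrow = m, ncol = n)
  for (j in seq_len(n)) {
    G[, j] <- rep(rep(0:2, each = 3L^(j - 1L)), length.out = m)
  }
  prior <- rep(1, m)
  fa_idx <- match(ped$father_id, ids)
  mo_idx <- match(ped$mother_id, ids)
  for (j in seq_len(n)) {
    if (is.na(fa_idx[j])) {
      prior <- prior * hw[G[, j] + 1L]
    } else {
      prior <- prior * tr[cbind(G[, fa_idx[j]] + 1L, G[, mo_idx[j]] + 1L, G[, j] + 1L)]
    }
  }
  for (id in names(clamped)) {
    j <- match(id, ids)
    if (is.na(j)) abort(paste0("clamp for unknown id: ", id))
    prior <- prior * clamp_indicator(clamped[[id]])[G[, j] + 1L]
  }
  keep <- if (drop_zero) prior > 0 else rep(TRUE, m)
  out <- as_tibble(as.data.frame(G[keep, , drop = FALSE]), .name_repair = "minimal")
  names(out) <- ids
  out$.prior <- prior[keep]
  out
}
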