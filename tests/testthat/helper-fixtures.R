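# Shared builders and brute-force oracles for the test suite.

library(tibble)
library(dplyr)
library(purrr)

make_individual <- function(id, father = NA, mother = NA, sex = "male",
                            proband = FALSE, test = "untested",
                            vital = "alive", alc = NA, death = NA,
                            cancers = NULL) {
  tibble(
    family_id = "f1", id = id,
    father_id = as.character(father), mother_id = as.character(mother),
    sex = sex, proband = proband, test = test, vital = vital,
    age_last_contact = as.numeric(alc), age_death = as.numeric(death),
    cancers = list(cancers %||% lfsrisk:::empty_cancers())
  )
}

cancer <- function(type, age = NA, idx = 1L, subtype = NA) {
  tibble(type = type, subtype = as.character(subtype),
         age_dx = as.numeric(age), primary_index = as.integer(idx))
}

make_trio <- function(child_cancers = NULL, child_test = "untested",
                      father_test = "untested", mother_test = "untested",
                      proband = "c") {
  as_lfs_pedigree(bind_rows(
    make_individual("p", sex = "male", test = father_test, alc = 60,
                    proband = proband == "p"),
    make_individual("m", sex = "female", test = mother_test, alc = 58,
                    proband = proband == "m"),
    make_individual("c", "p", "m", sex = "female", test = child_test,
                    alc = 30, cancers = child_cancers,
                    proband = proband == "c")
  ))
}

# random small pedigree via the structure simulator, capped at n members
random_small_pedigree <- function(max_n, min_n = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- cohort_config(n_families = 1, generations = 3, seed = 1)
  repeat {
    p <- simulate_structure(cfg, seed = sample.int(1e6, 1))
    if (nrow(p) <= max_n && nrow(p) >= min_n) return(p)
  }
}

random_tables <- function(ped) {
  setNames(map(seq_len(nrow(ped)), function(i) {
    v <- runif(2)
    c(v[1], v[2], v[2])
  }), ped$id)
}

# brute-force family likelihood by exhaustive enumeration
brute_likelihood <- function(ped, tabs, clamps = list(), f = 0.0006) {
  e <- enumerate_genotype_configs(ped, clamps, f = f)
  if (nrow(e) == 0) return(0)
  gm <- as.matrix(e[, ped$id])
  liks <- sapply(seq_len(nrow(ped)), function(j) {
    (tabs[[ped$id[j]]] %||% c(1, 1, 1))[gm[, j] + 1]
  })
  if (is.null(dim(liks))) liks <- matrix(liks, nrow = nrow(e))
  sum(e$.prior * apply(liks, 1, prod))
}

# brute-force carrier posterior
brute_posterior <- function(ped, tabs, target, clamps = list(), f = 0.0006) {
  e <- enumerate_genotype_configs(ped, clamps, f = f)
  gm <- as.matrix(e[, ped$id])
  liks <- sapply(seq_len(nrow(ped)), function(j) {
    (tabs[[ped$id[j]]] %||% c(1, 1, 1))[gm[, j] + 1]
  })
  if (is.null(dim(liks))) liks <- matrix(liks, nrow = nrow(e))
  w <- e$.prior * apply(liks, 1, prod)
  sum(w[gm[, match(target, ped$id)] >= 1]) / sum(w)
}

# O(n^2) pair-counting AUC oracle
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) {
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  s / (length(pos) * length(neg))
}

default_outcomes <- c("sarcoma", "breast", "other", "death")

random_cs_params <- function() {
  cs_params(
    shape = setNames(runif(4, 1, 4), default_outcomes),
    scale = setNames(runif(4, 80, 400), default_outcomes),
    beta_G = setNames(runif(4, 0, 3.5), default_outcomes),
    beta_S = setNames(runif(4, -0.5, 0.5), default_outcomes),
    beta_GxS = setNames(runif(4, -0.5, 0.5), default_outcomes),
    theta = runif(1, 0, 1)
  )
}

# founders-only cohort with known genotypes, convenient for calibration and
# generator-consistency checks
founder_cohort <- function(n, genotype = 1L, family_id = "x") {
  ped <- tibble(
    family_id = family_id, id = as.character(seq_len(n)),
    father_id = NA_character_, mother_id = NA_character_,
    sex = sample(c("male", "female"), n, replace = TRUE),
    proband = FALSE, test = "untested", vital = "unknown",
    age_last_contact = NA_real_, age_death = NA_real_,
    generation = 1L, genotype = as.integer(genotype)
  )
  ped$cancers <- rep(list(lfsrisk:::empty_cancers()), n)
  ped
}
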