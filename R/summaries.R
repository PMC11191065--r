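# Cohort summary tables: categorisation of family members by sex, number of
# primaries and mutation status; missingness-extent tables at family,
# individual, and first-degree-relatives-and-spouse levels; family-size
# percentiles.

# percentage formatting: nearest integer, one decimal below 1%
fmt_pct <- function(count, total) {
  if (total == 0) return("0")
  p <- 100 * count / total
  if (p > 0 && p < 1) sprintf("%.1f", p) else as.character(round(p))
}

obs_miss_category <- function(ped) {
  ped <- as_tibble(ped)
  cens_known <- !is.na(censor_age(ped))
  dx_missing <- map_lgl(ped$cancers, function(cc) {
    nrow(cc) > 0 && any(is.na(cc$age_dx))
  })
  case_when(
    cens_known & !dx_missing ~ "complete",
    !cens_known & !dx_missing ~ "alc",
    cens_known & dx_missing ~ "dx",
    TRUE ~ "both"
  )
}

miss_table <- function(categories) {
  lv <- c("complete", "alc", "dx", "both")
  counts <- vapply(lv, function(l) sum(categories == l), numeric(1))
  total <- length(categories)
  tibble(
    category = c("Complete data", "Missing age at last contact only",
                 "Missing age at cancer diagnosis only",
                 "Missing both age at last contact and age at cancer diagnosis"),
    n = unname(counts),
    pct = unname(vapply(counts, fmt_pct, character(1), total = total)),
    total = total
  )
}

# proband's first-degree relatives and spouses (co-parents of the proband's
# children); the proband is not counted
fdr_spouse_ids <- function(p) {
  pro <- p$id[p$proband][1]
  if (is.na(pro)) return(character())
  i <- match(pro, p$id)
  parents <- c(p$father_id[i], p$mother_id[i])
  sibs <- p$id[p$id != pro & !is.na(p$father_id) &
                 p$father_id %in% parents[1] & p$mother_id %in% parents[2]]
  kids <- p$id[!is.na(p$father_id) & (p$father_id == pro | p$mother_id == pro)]
  spouses <- unique(unlist(map(kids, function(k) {
    j <- match(k, p$id)
    setdiff(c(p$father_id[j], p$mother_id[j]), pro)
  })))
  setdiff(unique(c(parents[!is.na(parents)], sibs, kids, spouses)), NA)
}

#' Cohort summary tables
#'
#' Produces (1) a categorisation of family members by sex, number of primary
#' cancers (healthy / single / multiple) and mutation status (wildtype /
#' mutation / unknown) with subtotals; (2) missingness-extent tables — the
#' four categories complete, missing age at last contact only, missing
#' diagnosis age only, missing both — at the family level (a family takes the
#' kinds of missingness present among its members), the individual level, and
#' restricted to the probands' first-degree relatives and spouses; (3)
#' family-size percentiles. Percentages are rounded to the nearest integer,
#' with one decimal below 1%.
#'
#' @param cohort An `lfs_pedigree` cohort (may be empty).
#' @return An `lfs_cohort_summary` list: `by_status`, `family_missing`,
#'   `individual_missing`, `fdr_missing`, `family_size`.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  n_prim <- if (nrow(cohort)) map_dbl(cohort$cancers, nrow) else numeric()
  grp <- case_when(n_prim == 0 ~ "Healthy", n_prim == 1 ~ "SPC", TRUE ~ "MPC")
  status <- c(wildtype = "WT", carrier = "Mut", untested = "U")[cohort$test]
  cnt <- function(sex, g, st) {
    sum(cohort$sex == sex & grp == g & status == st)
  }
  rows <- list()
  for (sex in c("male", "female")) {
    for (g in c("Healthy", "SPC", "MPC")) {
      rows[[length(rows) + 1]] <- tibble(
        sex = sex, group = g,
        WT = cnt(sex, g, "WT"), Mut = cnt(sex, g, "Mut"), U = cnt(sex, g, "U"))
    }
    sub <- bind_rows(rows[(length(rows) - 2):length(rows)])
    rows[[length(rows) + 1]] <- tibble(
      sex = sex, group = "Subtotal",
      WT = sum(sub$WT), Mut = sum(sub$Mut), U = sum(sub$U))
  }
  by_status <- bind_rows(rows)
  by_status <- bind_rows(
    by_status,
    by_status %>% filter(.data$group == "Subtotal") %>%
      summarise(sex = "all", group = "Total",
                WT = sum(.data$WT), Mut = sum(.data$Mut), U = sum(.data$U)))
  by_status$Total <- by_status$WT + by_status$Mut + by_status$U

  indiv_cat <- if (nrow(cohort)) obs_miss_category(cohort) else character()
  fam_cat <- map_chr(split_families(cohort), function(p) {
    cats <- obs_miss_category(p)
    alc_any <- any(cats %in% c("alc", "both"))
    dx_any <- any(cats %in% c("dx", "both"))
    if (alc_any && dx_any) "both"
    else if (alc_any) "alc" else if (dx_any) "dx" else "complete"
  })
  fdr_cat <- unlist(map(split_families(cohort), function(p) {
    ids <- fdr_spouse_ids(p)
    if (length(ids) == 0) return(character())
    obs_miss_category(p[p$id %in% ids, ])
  }))
  sizes <- if (nrow(cohort)) {
    as.numeric(table(cohort$family_id))
  } else numeric()
  qs <- function(p) if (length(sizes)) unname(quantile(sizes, p)) else NA_real_
  family_size <- tibble(
    statistic = c("min", "p5", "p10", "p25", "median", "mean", "p75", "p90",
                  "p95", "max"),
    value = if (length(sizes)) {
      c(min(sizes), qs(.05), qs(.10), qs(.25), qs(.5), mean(sizes),
        qs(.75), qs(.90), qs(.95), max(sizes))
    } else rep(NA_real_, 10)
  )
  structure(
    list(by_status = by_status,
         family_missing = miss_table(fam_cat),
         individual_missing = miss_table(indiv_cat),
         fdr_missing = miss_table(fdr_cat %||% character()),
         family_size = family_size),
    class = "lfs_cohort_summary"
  )
}

#' @export
print.lfs_cohort_summary <- function(x, ...) {
  cat("Family members by sex, number of primaries and mutation status:\n")
  print(as.data.frame(x$by_status), row.names = FALSE)
  cat("\nMissingness, family level (n, %):\n")
  print(as.data.frame(x$family_missing), row.names = FALSE)
  cat("\nMissingness, individual level (n, %):\n")
  print(as.data.frame(x$individual_missing), row.names = FALSE)
  cat("\nMissingness, first-degree relatives and spouses (n, %):\n")
  print(as.data.frame(x$fdr_missing), row.names = FALSE)
  cat("\nIndividuals per family:\n")
  print(as.data.frame(x$family_size), row.names = FALSE)
  invisible(x)
}

#' Deterministic synthetic clinical-cohort fixture
#'
#' Builds, without randomness, a synthetic cohort of 124 families / 3,297
#' individuals whose summary margins match the published profile of a
#' clinical counseling cohort: the sex-by-primaries-by-status counts, the
#' individual-level missingness category counts (1748 complete / 1339 missing
#' age at last contact only / 138 missing diagnosis age only / 72 missing
#' both), and the family-level category counts (10 / 46 / 0 / 68). Used to
#' test the summary tables; the pedigree structure itself (all founders) is
#' deliberately minimal.
#'
#' @return An `lfs_pedigree` cohort.
#' @export
synthetic_clinical_fixture <- function() {
  # sex x group x (WT, Mut, U) counts
  spec <- tibble(
    sex = rep(c("male", "female"), each = 9),
    group = rep(rep(c("Healthy", "SPC", "MPC"), each = 3), 2),
    status = rep(c("wildtype", "carrier", "untested"), 6),
    n = c(17, 13, 1376, 3, 15, 210, 1, 10, 20,
          21, 20, 1203, 3, 33, 260, 1, 59, 32)
  )
  rows <- spec[rep(seq_len(nrow(spec)), spec$n), c("sex", "group", "status")]
  # assign missingness categories: the 210 diagnosis-age categories must go
  # to affected rows
  rows <- rows[order(rows$group == "Healthy"), ]  # affected first
  n <- nrow(rows)
  cat <- character(n)
  cat[1:72] <- "both"
  cat[73:210] <- "dx"
  cat[211:(210 + 1339)] <- "alc"
  cat[(210 + 1339 + 1):n] <- "complete"
  rows$miss <- cat
  # family assignment: families 1-10 all-complete; 11-56 contain alc-missing
  # only; 57-124 contain both kinds
  fam <- integer(n)
  comp_i <- which(rows$miss == "complete")
  fam[comp_i[1:124]] <- 1:124           # one complete member (the proband) each
  dx_i <- which(rows$miss %in% c("dx", "both"))
  fam[dx_i] <- 57 + (seq_along(dx_i) - 1) %% 68
  alc_i <- which(rows$miss == "alc")
  fam[alc_i] <- 11 + (seq_along(alc_i) - 1) %% 114
  rest <- comp_i[-(1:124)]
  fam[rest] <- 1 + (seq_along(rest) - 1) %% 124
  rows$family_id <- paste0("cf", fam)
  rows$proband <- FALSE
  rows$proband[comp_i[1:124]] <- TRUE
  out <- rows %>%
    group_by(.data$family_id) %>%
    mutate(id = as.character(row_number())) %>%
    ungroup()
  out$father_id <- NA_character_
  out$mother_id <- NA_character_
  out$test <- out$status
  out$vital <- "alive"
  out$age_last_contact <- ifelse(out$miss %in% c("alc", "both"), NA_real_, 50)
  out$age_death <- NA_real_
  mk_cc <- function(group, miss, sex) {
    if (group == "Healthy") return(empty_cancers())
    dx <- if (miss %in% c("dx", "both")) NA_real_ else 30
    type1 <- if (sex == "female" && group == "SPC") "breast" else "other"
    cc <- tibble(type = type1, subtype = NA_character_, age_dx = dx,
                 primary_index = 1L)
    if (group == "MPC") {
      cc <- bind_rows(cc, tibble(
        type = "other", subtype = NA_character_,
        age_dx = if (is.na(dx)) NA_real_ else 40, primary_index = 2L))
    }
    cc
  }
  out$cancers <- pmap(list(out$group, out$miss, out$sex), mk_cc)
  out$miss_category <- out$miss
  as_lfs_pedigree(out[, c("family_id", "id", "father_id", "mother_id", "sex",
                          "proband", "test", "vital", "age_last_contact",
                          "age_death", "cancers", "miss_category")])
}
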