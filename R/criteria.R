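# Classic and Chompret clinical testing criteria, used as rule-based
# comparator classifiers. Age-bounded clauses are never satisfied by unknown
# ages; clauses that need tumour subtypes (adrenocortical, choroid plexus,
# CNS, anaplastic rhabdomyosarcoma) read the optional subtype tags of the
# pedigree format, and an untagged "other" cancer never satisfies a
# subtype-specific clause.

# relatives of `id` with degree and parental-side sets
relative_map <- function(ped, id) {
  ped <- as_tibble(ped)
  idx <- setNames(seq_len(nrow(ped)), ped$id)
  fa <- function(x) ped$father_id[idx[[x]]]
  mo <- function(x) ped$mother_id[idx[[x]]]
  kids <- function(x) ped$id[!is.na(ped$father_id) &
                               (ped$father_id == x | ped$mother_id == x)]
  sibs <- function(x) {
    if (is.na(fa(x))) return(character())
    ped$id[ped$id != x & !is.na(ped$father_id) &
             ped$father_id == fa(x) & ped$mother_id == mo(x)]
  }
  half_sibs <- function(x) {
    if (is.na(fa(x))) return(character())
    ped$id[ped$id != x & !is.na(ped$father_id) &
             (ped$father_id == fa(x)) != (ped$mother_id == mo(x))]
  }
  out <- list()
  add <- function(ids, degree, side) {
    for (r in ids) {
      if (is.na(r) || !r %in% ped$id) next
      out[[r]] <<- list(degree = min(degree, out[[r]]$degree %||% 99L),
                        side = union(side, out[[r]]$side))
    }
  }
  # first degree
  add(fa(id), 1L, "paternal"); add(mo(id), 1L, "maternal")
  add(sibs(id), 1L, c("paternal", "maternal"))
  add(kids(id), 1L, c("paternal", "maternal"))
  # second degree
  if (!is.na(fa(id))) {
    add(c(fa(fa(id)), mo(fa(id))), 2L, "paternal")
    add(sibs(fa(id)), 2L, "paternal")
    add(c(fa(mo(id)), mo(mo(id))), 2L, "maternal")
    add(sibs(mo(id)), 2L, "maternal")
    add(half_sibs(id), 2L, c("paternal", "maternal"))
  }
  for (s in sibs(id)) add(kids(s), 2L, c("paternal", "maternal"))
  for (k in kids(id)) add(kids(k), 2L, c("paternal", "maternal"))
  out
}

events_of <- function(ped, id) {
  ped$cancers[[match(id, ped$id)]]
}

has_cancer_before <- function(cc, age) {
  any(!is.na(cc$age_dx) & cc$age_dx < age)
}

has_sarcoma <- function(cc, before = Inf) {
  sel <- cc$type == "sarcoma"
  if (is.finite(before)) sel <- sel & !is.na(cc$age_dx) & cc$age_dx < before
  any(sel)
}

#' Classic (Li-Fraumeni) criteria
#'
#' TRUE when the proband has a sarcoma diagnosed before age 45, a
#' first-degree relative has any cancer before 45, and another first- or
#' second-degree relative in the same lineage has any cancer before 45 or a
#' sarcoma at any age. "Same lineage" is operationalised through parental-side
#' sets (paternal-side second-degree relatives {paternal}, maternal-side
#' {maternal}, siblings and descendants both); two relatives qualify together
#' when their side sets intersect. Unknown ages never satisfy an age-bounded
#' clause.
#'
#' @param ped An `lfs_pedigree` holding one family.
#' @param proband Proband id (default: the flagged proband).
#' @return Logical scalar; attribute `"rule"` names the firing rule.
#' @export
classic_criteria <- function(ped, proband = NULL) {
  ped <- one_family(as_tibble(ped))
  proband <- proband %||% ped$id[ped$proband][1]
  if (is.na(proband)) abort("no proband")
  if (!has_sarcoma(events_of(ped, proband), before = 45)) {
    return(structure(FALSE, rule = "none"))
  }
  rel <- relative_map(ped, proband)
  fdr_hits <- names(keep(rel, function(r) r$degree == 1L))
  fdr_hits <- fdr_hits[map_lgl(fdr_hits, function(r) {
    has_cancer_before(events_of(ped, r), 45)
  })]
  for (r1 in fdr_hits) {
    side1 <- rel[[r1]]$side
    others <- setdiff(names(rel), r1)
    for (r2 in others) {
      if (length(intersect(side1, rel[[r2]]$side)) == 0) next
      cc2 <- events_of(ped, r2)
      if (has_cancer_before(cc2, 45) || has_sarcoma(cc2)) {
        return(structure(TRUE, rule = "classic"))
      }
    }
  }
  structure(FALSE, rule = "none")
}

# LFS tumour spectrum for the Chompret clauses: soft-tissue/osteosarcoma,
# premenopausal breast cancer (operationalised as diagnosis before 50), CNS
# tumours, adrenocortical carcinoma.
in_spectrum <- function(type, subtype, age_dx) {
  (type == "sarcoma") |
    (type == "breast" & !is.na(age_dx) & age_dx < 50) |
    (!is.na(subtype) & subtype %in% c("CNS", "ACC"))
}

#' Chompret criteria (2009 / 2015 revisions)
#'
#' TRUE when any clause holds: (i) proband with an LFS-spectrum tumour before
#' 46 and at least one first/second-degree relative with an LFS-spectrum
#' tumour before 56 or with multiple primaries; (ii) proband with multiple
#' primaries, at least two in the spectrum, the first before 46; (iii)
#' adrenocortical carcinoma or (2015) choroid-plexus tumour at any age; (iv)
#' (2015 only) breast cancer before 31. The spectrum comprises
#' soft-tissue/osteosarcoma, premenopausal breast cancer (before 50), CNS
#' tumours and adrenocortical carcinoma; subtype-specific clauses require the
#' corresponding subtype tag.
#'
#' @inheritParams classic_criteria
#' @param version `"2015"` (default) or `"2009"`.
#' @return Logical scalar; attribute `"rule"` names the firing clause.
#' @export
chompret_criteria <- function(ped, proband = NULL, version = c("2015", "2009")) {
  version <- match.arg(version)
  ped <- one_family(as_tibble(ped))
  proband <- proband %||% ped$id[ped$proband][1]
  if (is.na(proband)) abort("no proband")
  cc <- events_of(ped, proband)
  # clause iii: adrenocortical (any revision) / choroid plexus (2015)
  iii_tags <- if (version == "2015") c("ACC", "CPT") else "ACC"
  if (any(!is.na(cc$subtype) & cc$subtype %in% iii_tags)) {
    return(structure(TRUE, rule = "chompret-iii"))
  }
  # clause iv (2015): breast cancer before 31
  if (version == "2015" &&
      any(cc$type == "breast" & !is.na(cc$age_dx) & cc$age_dx < 31)) {
    return(structure(TRUE, rule = "chompret-iv"))
  }
  spec <- in_spectrum(cc$type, cc$subtype, cc$age_dx)
  # clause ii: MPC proband, >= 2 in spectrum, first before 46
  if (nrow(cc) >= 2 && sum(spec) >= 2) {
    t1 <- cc$age_dx[cc$primary_index == 1]
    if (length(t1) == 1 && !is.na(t1) && t1 < 46) {
      return(structure(TRUE, rule = "chompret-ii"))
    }
  }
  # clause i
  pro_i <- any(spec & !is.na(cc$age_dx) & cc$age_dx < 46)
  if (pro_i) {
    rel <- relative_map(ped, proband)
    for (r in names(rel)) {
      rc <- events_of(ped, r)
      if (nrow(rc) == 0) next
      rspec <- in_spectrum(rc$type, rc$subtype, rc$age_dx)
      if (any(rspec & !is.na(rc$age_dx) & rc$age_dx < 56) || nrow(rc) >= 2) {
        return(structure(TRUE, rule = "chompret-i"))
      }
    }
  }
  structure(FALSE, rule = "none")
}
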