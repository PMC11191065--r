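#' Pedigree tibbles
#'
#' A pedigree is stored as a tibble of class `lfs_pedigree` with one row per
#' individual and the columns
#'
#' * `family_id`, `id` — character identifiers (`id` unique within family),
#' * `father_id`, `mother_id` — character or `NA`; both present or both absent,
#' * `sex` — `"male"` or `"female"` (never missing),
#' * `proband` — logical, exactly one `TRUE` per family,
#' * `test` — `"carrier"`, `"wildtype"` or `"untested"` (TP53 germline test),
#' * `vital` — `"alive"`, `"dead"` or `"unknown"`,
#' * `age_last_contact`, `age_death` — years (continuous, 0-based) or `NA`,
#' * `cancers` — list-column of tibbles with `type` (`"sarcoma"`, `"breast"`,
#'   `"other"`), `subtype` (`NA` or a tag such as `"ACC"`, `"CPT"`, `"CNS"`,
#'   `"RMS"`), `age_dx` (years or `NA`) and `primary_index` (1, 2, ...).
#'
#' A single `lfs_pedigree` may hold several families (a cohort); per-family
#' operations split on `family_id`. Simulated cohorts carry extra columns
#' (`genotype`, `miss_category`) which readers/writers ignore.
#'
#' @param x A data frame with the columns above (`cancers` optional).
#' @param validate If `TRUE`, structural issues raise an error.
#' @return An `lfs_pedigree` tibble.
#' @export
as_lfs_pedigree <- function(x, validate = TRUE) {
  x <- as_tibble(x)
  need <- c("family_id", "id", "father_id", "mother_id", "sex")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(paste0("pedigree is missing columns: ", paste(miss, collapse = ", ")))
  }
  defaults <- list(
    proband = FALSE, test = "untested", vital = "unknown",
    age_last_contact = NA_real_, age_death = NA_real_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(x)) x[[nm]] <- defaults[[nm]]
  }
  if (!"cancers" %in% names(x)) {
    x$cancers <- rep(list(empty_cancers()), nrow(x))
  }
  x$cancers <- map(x$cancers, function(cc) {
    cc <- as_tibble(cc %||% empty_cancers())
    if (nrow(cc) == 0) return(empty_cancers())
    if (!"subtype" %in% names(cc)) cc$subtype <- NA_character_
    cc$age_dx <- as.numeric(cc$age_dx)
    cc$primary_index <- as.integer(cc$primary_index)
    cc[order(cc$primary_index), c("type", "subtype", "age_dx", "primary_index")]
  })
  for (nm in c("family_id", "id", "father_id", "mother_id")) {
    x[[nm]] <- as.character(x[[nm]])
  }
  x$age_last_contact <- as.numeric(x$age_last_contact)
  x$age_death <- as.numeric(x$age_death)
  x$proband <- as.logical(x$proband)
  class(x) <- c("lfs_pedigree", class(x))
  if (validate) {
    issues <- validate_pedigree(x)
    if (nrow(issues) > 0) {
      abort(paste0(
        "invalid pedigree:\n",
        paste0("  [", issues$family_id, "/", issues$id, "] ", issues$rule,
               ": ", issues$message, collapse = "\n")
      ))
    }
  }
  x
}

empty_cancers <- function() {
  tibble(type = character(), subtype = character(),
         age_dx = numeric(), primary_index = integer())
}

#' Structural validation of a pedigree
#'
#' Checks the pedigree invariants: unique ids, both-or-none parent references
#' that resolve within the family, acyclic ancestry, fathers male / mothers
#' female, exactly one proband per family, valid factor levels, cancer events
#' with consecutive primary indices and diagnosis ages not after death, and
#' breast cancer restricted to females (a warning-level issue).
#'
#' @param ped An `lfs_pedigree` (or coercible data frame).
#' @return A tibble of issues (`family_id`, `id`, `rule`, `message`); zero rows
#'   when all invariants hold. Issues are returned, never raised.
#' @export
validate_pedigree <- function(ped) {
  ped <- as_tibble(ped)
  out <- list()
  note <- function(fam, id, rule, message) {
    out[[length(out) + 1]] <<- tibble(
      family_id = fam, id = id, rule = rule, message = message
    )
  }
  for (fam in unique(ped$family_id)) {
    p <- ped[ped$family_id == fam, ]
    dup <- p$id[duplicated(p$id)]
    for (d in unique(dup)) note(fam, d, "duplicate id", "id appears more than once")
    if (sum(p$proband, na.rm = TRUE) > 1) {
      note(fam, paste(p$id[which(p$proband)], collapse = ","),
           "multiple probands", "more than one proband flagged")
    }
    bad_sex <- p$id[!p$sex %in% c("male", "female")]
    for (d in bad_sex) note(fam, d, "invalid sex", "sex must be male or female")
    for (i in seq_len(nrow(p))) {
      fa <- p$father_id[i]; mo <- p$mother_id[i]
      if (is.na(fa) != is.na(mo)) {
        note(fam, p$id[i], "single-parent reference",
             "father and mother must both be given or both be missing")
        next
      }
      if (!is.na(fa)) {
        if (!fa %in% p$id) {
          note(fam, p$id[i], "unresolved parent", paste0("father '", fa, "' not in family"))
        } else if (p$sex[match(fa, p$id)] != "male") {
          note(fam, p$id[i], "father not male", paste0("father '", fa, "' is not male"))
        }
        if (!mo %in% p$id) {
          note(fam, p$id[i], "unresolved parent", paste0("mother '", mo, "' not in family"))
        } else if (p$sex[match(mo, p$id)] != "female") {
          note(fam, p$id[i], "mother not female", paste0("mother '", mo, "' is not female"))
        }
      }
      cc <- p$cancers[[i]]
      if (nrow(cc) > 0) {
        if (!identical(sort(cc$primary_index), seq_len(nrow(cc)))) {
          note(fam, p$id[i], "primary index", "primary_index must be consecutive from 1")
        }
        known <- cc$age_dx[!is.na(cc$age_dx)]
        if (!is.na(p$age_death[i]) && length(known) > 0 &&
            p$age_death[i] < max(known) - 1e-9) {
          note(fam, p$id[i], "death before diagnosis",
               "age_death earlier than a known diagnosis age")
        }
        if (any(cc$type == "breast") && p$sex[i] == "male") {
          note(fam, p$id[i], "male breast event", "breast cancer recorded for a male")
        }
      }
    }
    # cycle check over resolvable parent edges
    idx <- setNames(seq_len(nrow(p)), p$id)
    colr <- rep(0L, nrow(p))  # 0 unseen, 1 active, 2 done
    cyc <- FALSE
    visit <- function(i) {
      if (colr[i] == 1L) { cyc <<- TRUE; return() }
      if (colr[i] == 2L) return()
      colr[i] <<- 1L
      for (par in c(p$father_id[i], p$mother_id[i])) {
        if (!is.na(par) && par %in% names(idx)) visit(idx[[par]])
      }
      colr[i] <<- 2L
    }
    for (i in seq_len(nrow(p))) visit(i)
    if (cyc) note(fam, NA_character_, "cyclic ancestry", "parent graph contains a cycle")
  }
  if (length(out) == 0) {
    tibble(family_id = character(), id = character(),
           rule = character(), message = character())
  } else {
    bind_rows(out)
  }
}

# --- file I/O ----------------------------------------------------------------

MISSING_PED <- c("-9", "")

fmt_ped_num <- function(x) {
  ifelse(is.na(x), "-9",
         format(x, trim = TRUE, scientific = FALSE, digits = 17))
}

cancer_token <- function(type, subtype) {
  code <- c(sarcoma = "SA", breast = "BR", other = "OT")[type]
  ifelse(is.na(subtype), code, paste0(code, ":", subtype))
}

parse_cancer_token <- function(tok, row) {
  parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
  type <- c(SA = "sarcoma", BR = "breast", OT = "other")[parts[1]]
  if (is.na(type)) {
    abort(paste0("row ", row, ": unknown cancer type token '", tok, "'"))
  }
  list(type = unname(type),
       subtype = if (length(parts) > 1) parts[2] else NA_character_)
}

#' Read a pedigree file
#'
#' Two plain-text dialects are supported.
#'
#' **ped**: tab-delimited, no header; columns `family_id`, `id`, `father_id`,
#' `mother_id` (0 = founder), `sex` (1 = male, 2 = female), `proband` (0/1),
#' `test` (0 = untested, 1 = carrier, 2 = wildtype), `vital` (0 = alive,
#' 1 = dead, 9 = unknown), `age_last_contact`, `age_death` (-9 = missing),
#' followed by repeated triplets `cancer_type age_dx primary_index` where
#' `cancer_type` is `SA`, `BR` or `OT` with an optional subtype suffix
#' (e.g. `OT:ACC`).
#'
#' **csv**: long-format CSV with a header; `record` column distinguishes
#' `individual` rows (all per-person fields) from `cancer` rows (one event per
#' row, keyed by `family_id` + `id`). Missing values are empty fields.
#'
#' @param path Path to the file.
#' @param dialect `"ped"` or `"csv"`.
#' @return An `lfs_pedigree` tibble (validated; structural violations such as
#'   single-parent references are errors naming the offending row).
#' @export
read_pedigree <- function(path, dialect = c("ped", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (dialect == "ped") read_pedigree_ped(path) else read_pedigree_csv(path)
}

read_pedigree_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- map(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 10) abort(paste0("row ", i, ": expected at least 10 fields"))
    num <- function(s) ifelse(s %in% MISSING_PED, NA_real_, as.numeric(s))
    cc <- empty_cancers()
    if (length(f) > 10) {
      extra <- f[-(1:10)]
      if (length(extra) %% 3 != 0) {
        abort(paste0("row ", i, ": cancer fields not in triplets"))
      }
      k <- length(extra) / 3
      cc <- map(seq_len(k), function(j) {
        tok <- parse_cancer_token(extra[3 * j - 2], i)
        tibble(type = tok$type, subtype = tok$subtype,
               age_dx = num(extra[3 * j - 1]),
               primary_index = as.integer(extra[3 * j]))
      }) %>% bind_rows()
    }
    tibble(
      family_id = f[1], id = f[2],
      father_id = ifelse(f[3] == "0", NA_character_, f[3]),
      mother_id = ifelse(f[4] == "0", NA_character_, f[4]),
      sex = unname(c("1" = "male", "2" = "female")[f[5]]),
      proband = f[6] == "1",
      test = unname(c("0" = "untested", "1" = "carrier", "2" = "wildtype")[f[7]]),
      vital = unname(c("0" = "alive", "1" = "dead", "9" = "unknown")[f[8]]),
      age_last_contact = num(f[9]),
      age_death = num(f[10]),
      cancers = list(cc)
    )
  })
  as_lfs_pedigree(bind_rows(rows))
}

read_pedigree_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  ind <- raw[raw$record == "individual", ]
  can <- raw[raw$record == "cancer", ]
  num <- function(s) ifelse(is.na(s) | s == "", NA_real_, as.numeric(s))
  ped <- tibble(
    family_id = ind$family_id, id = ind$id,
    father_id = ifelse(is.na(ind$father_id) | ind$father_id == "", NA_character_, ind$father_id),
    mother_id = ifelse(is.na(ind$mother_id) | ind$mother_id == "", NA_character_, ind$mother_id),
    sex = ind$sex, proband = ind$proband == "1",
    test = ind$test, vital = ind$vital,
    age_last_contact = num(ind$age_last_contact),
    age_death = num(ind$age_death)
  )
  ped$cancers <- map2(ped$family_id, ped$id, function(fam, id) {
    cc <- can[can$family_id == fam & can$id == id, ]
    if (nrow(cc) == 0) return(empty_cancers())
    tibble(type = cc$cancer_type,
           subtype = ifelse(is.na(cc$subtype) | cc$subtype == "", NA_character_, cc$subtype),
           age_dx = num(cc$age_dx),
           primary_index = as.integer(cc$primary_index))
  })
  as_lfs_pedigree(ped)
}

#' Write a pedigree file
#'
#' Inverse of [read_pedigree()]; `read_pedigree(write_pedigree(ped, f), d)`
#' reproduces `ped` field-for-field in both dialects.
#'
#' @param ped An `lfs_pedigree`.
#' @param path Output path.
#' @param dialect `"ped"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, dialect = c("ped", "csv")) {
  dialect <- match.arg(dialect)
  ped <- as_tibble(ped)
  if (dialect == "ped") {
    lines <- map_chr(seq_len(nrow(ped)), function(i) {
      cc <- ped$cancers[[i]]
      trip <- if (nrow(cc) > 0) {
        unlist(map(seq_len(nrow(cc)), function(j) {
          c(cancer_token(cc$type[j], cc$subtype[j]),
            fmt_ped_num(cc$age_dx[j]), as.character(cc$primary_index[j]))
        }))
      } else character()
      paste(c(
        ped$family_id[i], ped$id[i],
        ifelse(is.na(ped$father_id[i]), "0", ped$father_id[i]),
        ifelse(is.na(ped$mother_id[i]), "0", ped$mother_id[i]),
        c(male = "1", female = "2")[ped$sex[i]],
        ifelse(isTRUE(ped$proband[i]), "1", "0"),
        c(untested = "0", carrier = "1", wildtype = "2")[ped$test[i]],
        c(alive = "0", dead = "1", unknown = "9")[ped$vital[i]],
        fmt_ped_num(ped$age_last_contact[i]), fmt_ped_num(ped$age_death[i]),
        trip
      ), collapse = "\t")
    })
    writeLines(lines, path)
  } else {
    chr <- function(x) {
      if (is.numeric(x)) {
        ifelse(is.na(x), "",
               format(x, trim = TRUE, scientific = FALSE, digits = 17))
      } else {
        ifelse(is.na(x), "", as.character(x))
      }
    }
    ind <- tibble(
      record = "individual",
      family_id = ped$family_id, id = ped$id,
      father_id = chr(ped$father_id), mother_id = chr(ped$mother_id),
      sex = ped$sex, proband = ifelse(ped$proband, "1", "0"),
      test = ped$test, vital = ped$vital,
      age_last_contact = chr(ped$age_last_contact),
      age_death = chr(ped$age_death),
      cancer_type = "", subtype = "", age_dx = "", primary_index = ""
    )
    can <- map(seq_len(nrow(ped)), function(i) {
      cc <- ped$cancers[[i]]
      if (nrow(cc) == 0) return(NULL)
      tibble(
        record = "cancer",
        family_id = ped$family_id[i], id = ped$id[i],
        father_id = "", mother_id = "", sex = "", proband = "",
        test = "", vital = "", age_last_contact = "", age_death = "",
        cancer_type = cc$type, subtype = chr(cc$subtype),
        age_dx = chr(cc$age_dx), primary_index = as.character(cc$primary_index)
      )
    }) %>% bind_rows()
    readr::write_csv(bind_rows(ind, can), path, progress = FALSE)
  }
  invisible(path)
}

# --- small structural helpers ------------------------------------------------

founders <- function(ped) ped$id[is.na(ped$father_id)]

one_family <- function(ped, family_id = NULL) {
  fams <- unique(ped$family_id)
  if (is.null(family_id)) {
    if (length(fams) > 1) abort("multiple families present; give family_id")
    family_id <- fams
  }
  ped[ped$family_id == family_id, ]
}

split_families <- function(ped) {
  split(as_tibble(ped), ped$family_id)
}

#' @export
print.lfs_pedigree <- function(x, ...) {
  if ("family_id" %in% names(x)) {
    nfam <- length(unique(x$family_id))
    cat("<lfs_pedigree> ", nrow(x), " individuals in ", nfam,
        if (nfam == 1) " family\n" else " families\n", sep = "")
  }
  NextMethod()
}
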