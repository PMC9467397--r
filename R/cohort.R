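#' Cohort configuration for the synthetic family study
#'
#' Defines the family composition and covariate distributions of the
#' synthetic cohort. The defaults reconstruct a design of 59 families with
#' 130 phenotyped members — 47 two-member and 12 three-member families whose
#' within-family relative-pair census is 55 full-sibling, 19 parent-child,
#' 8 avuncular and 1 half-sibling pair. Two-member families split into 39
#' sibling pairs, 7 parent-child pairs and 1 half-sibling pair; three-member
#' families into 2 sets of three siblings, 2 parent-with-two-children and 8
#' sibling-pairs-where-one-sibling-has-a-child (the unique-enough template
#' mix reproducing that census under those family sizes). Covariate
#' prevalences and moments default to the study sample: 54.6% female, 16.9%
#' APOE e4 carriers, BMI 25.6 (SD 3.9), hypertension 80.8%, diabetes 10%,
#' hypercholesterolemia 84.6%, ever-smokers 45.4%, ages 38-85 with median
#' near 72.
#'
#' @param family_templates named integer vector of template counts. Names:
#'   `sib_pair`, `parent_child`, `half_sib_pair` (two-member);
#'   `three_siblings`, `parent_two_children`, `sibpair_child_of_one`
#'   (three-member).
#' @param covariates named list of prevalences/moments; see defaults.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    family_templates = c(sib_pair = 39L, parent_child = 7L,
                         half_sib_pair = 1L, three_siblings = 2L,
                         parent_two_children = 2L, sibpair_child_of_one = 8L),
    covariates = list(
      female = 0.546, apoe4 = 0.169,
      bmi_mean = 25.6, bmi_sd = 3.9,
      hypertension = 0.808, diabetes = 0.10,
      hypercholesterolemia = 0.846, smoking = 0.454,
      age_min = 38, age_max = 85
    )) {
  templates <- c(sib_pair = 0L, parent_child = 0L, half_sib_pair = 0L,
                 three_siblings = 0L, parent_two_children = 0L,
                 sibpair_child_of_one = 0L)
  unknown <- setdiff(names(family_templates), names(templates))
  if (length(unknown) > 0)
    stop("unknown family template(s): ", paste(unknown, collapse = ", "))
  templates[names(family_templates)] <- as.integer(family_templates)
  prev <- unlist(covariates[c("female", "apoe4", "hypertension", "diabetes",
                              "hypercholesterolemia", "smoking")])
  if (any(prev < 0 | prev > 1))
    stop("prevalences must lie in [0, 1]")
  structure(list(family_templates = templates, covariates = covariates),
            class = "cohort_config")
}

# members per template (phenotyped)
template_sizes <- c(sib_pair = 2L, parent_child = 2L, half_sib_pair = 2L,
                    three_siblings = 3L, parent_two_children = 3L,
                    sibpair_child_of_one = 3L)

#' Build the synthetic-cohort pedigree fixture
#'
#' Deterministically expands the family templates of a [cohort_config()] into
#' a [pedigree]. No randomness is involved: the same config always yields the
#' same pedigree. Unphenotyped placeholder founders are inserted wherever a
#' relationship needs a common ancestor (e.g. the parents of a sibling pair
#' that were never examined); phenotyped parents in parent-child templates
#' alternate male/female so both roles occur.
#'
#' @param config a [cohort_config()].
#' @return A [pedigree]. With the default config: 130 phenotyped members in
#'   59 families, pair census 55/19/8/1 (sib / parent-child / avuncular /
#'   half-sib).
#' @export
build_fixture <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  tpl <- config$family_templates
  rows <- list()
  fam_i <- 0L
  pc_parent_male <- TRUE  # alternate sex of phenotyped parents
  add <- function(fid, id, father, mother, sex, phen) {
    data.frame(fid = fid, id = paste0(fid, "_", id),
               father = if (is.na(father)) NA_character_
                        else paste0(fid, "_", father),
               mother = if (is.na(mother)) NA_character_
                        else paste0(fid, "_", mother),
               sex = sex, phenotyped = phen, stringsAsFactors = FALSE)
  }
  for (tname in names(tpl)) {
    for (k in seq_len(tpl[[tname]])) {
      fam_i <- fam_i + 1L
      fid <- sprintf("F%03d", fam_i)
      fam <- switch(tname,
        sib_pair = rbind(
          add(fid, "p1", NA, NA, "male", FALSE),
          add(fid, "p2", NA, NA, "female", FALSE),
          add(fid, "s1", "p1", "p2", "unknown", TRUE),
          add(fid, "s2", "p1", "p2", "unknown", TRUE)
        ),
        parent_child = {
          psex <- if (pc_parent_male) "male" else "female"
          pc_parent_male <<- !pc_parent_male
          rbind(
            add(fid, "p1", NA, NA, psex, TRUE),
            add(fid, "c1", if (psex == "male") "p1" else NA,
                if (psex == "female") "p1" else NA, "unknown", TRUE)
          )
        },
        half_sib_pair = rbind(
          add(fid, "p1", NA, NA, "female", FALSE),
          add(fid, "h1", NA, "p1", "unknown", TRUE),
          add(fid, "h2", NA, "p1", "unknown", TRUE)
        ),
        three_siblings = rbind(
          add(fid, "p1", NA, NA, "male", FALSE),
          add(fid, "p2", NA, NA, "female", FALSE),
          add(fid, "s1", "p1", "p2", "unknown", TRUE),
          add(fid, "s2", "p1", "p2", "unknown", TRUE),
          add(fid, "s3", "p1", "p2", "unknown", TRUE)
        ),
        parent_two_children = {
          psex <- if (pc_parent_male) "male" else "female"
          pc_parent_male <<- !pc_parent_male
          ssex <- if (psex == "male") "female" else "male"
          rbind(
            add(fid, "p1", NA, NA, psex, TRUE),
            add(fid, "sp", NA, NA, ssex, FALSE),
            add(fid, "c1", if (psex == "male") "p1" else "sp",
                if (psex == "male") "sp" else "p1", "unknown", TRUE),
            add(fid, "c2", if (psex == "male") "p1" else "sp",
                if (psex == "male") "sp" else "p1", "unknown", TRUE)
          )
        },
        sibpair_child_of_one = {
          psex <- if (pc_parent_male) "male" else "female"
          pc_parent_male <<- !pc_parent_male
          rbind(
            add(fid, "g1", NA, NA, "male", FALSE),
            add(fid, "g2", NA, NA, "female", FALSE),
            add(fid, "s1", "g1", "g2", psex, TRUE),
            add(fid, "s2", "g1", "g2", "unknown", TRUE),
            add(fid, "c1", if (psex == "male") "s1" else NA,
                if (psex == "female") "s1" else NA, "unknown", TRUE)
          )
        },
        stop("unknown template: ", tname)
      )
      rows[[fam_i]] <- fam
    }
  }
  if (length(rows) == 0) {
    return(validate_pedigree(data.frame(
      fid = character(0), id = character(0), father = character(0),
      mother = character(0), sex = character(0), phenotyped = logical(0),
      stringsAsFactors = FALSE
    )))
  }
  validate_pedigree(do.call(rbind, rows))
}

#' Replicate a pedigree into disjoint copies
#'
#' Makes `k` disjoint copies of a pedigree with namespaced family and
#' individual ids; the kinship matrix of the result is block-diagonal and
#' members of different copies are unrelated. Used to scale up the fixture
#' for parameter-recovery simulations.
#'
#' @param ped a [pedigree].
#' @param k number of copies, >= 1.
#' @return A [pedigree] with `k * nrow(ped)` members.
#' @export
replicate_pedigree <- function(ped, k) {
  stopifnot(is_pedigree(ped))
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != round(k))
    stop("k must be an integer >= 1")
  k <- as.integer(k)
  if (k == 1L) return(ped)
  copies <- lapply(seq_len(k), function(i) {
    ns <- function(x) ifelse(is.na(x), NA_character_, paste0("r", i, ".", x))
    data.frame(fid = paste0("r", i, ".", ped$fid), id = ns(ped$id),
               father = ns(ped$father), mother = ns(ped$mother),
               sex = ped$sex, phenotyped = ped$phenotyped,
               stringsAsFactors = FALSE)
  })
  validate_pedigree(do.call(rbind, copies))
}
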