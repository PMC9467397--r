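#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `fid` (family id), `id` (individual id, unique across the whole pedigree),
#' `father`, `mother` (ids or `NA` for unknown), `sex`
#' (`"male"`, `"female"` or `"unknown"`) and `phenotyped` (logical).
#' Individuals with both parents unknown are founders. Parents referenced by
#' id must be present as members; unphenotyped placeholder founders are the
#' standard way to connect e.g. a sibling pair whose parents were never
#' examined.
#'
#' @param fid,id character vectors of family and individual ids.
#' @param father,mother character vectors of parent ids; `NA` = unknown.
#' @param sex character vector in `c("male", "female", "unknown")`.
#' @param phenotyped logical vector.
#' @return An object of class `pedigree` (a validated data frame).
#' @export
pedigree <- function(fid, id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", phenotyped = TRUE) {
  ped <- data.frame(
    fid = as.character(fid),
    id = as.character(id),
    father = as.character(father),
    mother = as.character(mother),
    sex = as.character(sex),
    phenotyped = as.logical(phenotyped),
    stringsAsFactors = FALSE
  )
  validate_pedigree(ped)
}

#' @rdname pedigree
#' @param x object to test or validate.
#' @export
is_pedigree <- function(x) inherits(x, "pedigree")

validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped))
  need <- c("fid", "id", "father", "mother", "sex", "phenotyped")
  miss <- setdiff(need, names(ped))
  if (length(miss) > 0)
    stop("pedigree is missing columns: ", paste(miss, collapse = ", "))
  dup <- ped$id[duplicated(ped$id)]
  if (length(dup) > 0)
    stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "))
  bad_sex <- setdiff(unique(ped$sex), c("male", "female", "unknown"))
  if (length(bad_sex) > 0)
    stop("invalid sex code(s): ", paste(bad_sex, collapse = ", "))
  for (col in c("father", "mother")) {
    ref <- ped[[col]][!is.na(ped[[col]])]
    absent <- setdiff(ref, ped$id)
    if (length(absent) > 0)
      stop("referenced ", col, "(s) absent from pedigree: ",
           paste(unique(absent), collapse = ", "))
  }
  # parents must belong to the same family as the child
  for (col in c("father", "mother")) {
    has <- !is.na(ped[[col]])
    pf <- ped$fid[match(ped[[col]][has], ped$id)]
    if (any(pf != ped$fid[has]))
      stop("parent in a different family for individual(s): ",
           paste(ped$id[has][pf != ped$fid[has]], collapse = ", "))
  }
  ord <- topological_order(ped)  # errors on cycles
  attr(ped, "topo_order") <- ord
  class(ped) <- unique(c("pedigree", class(ped)))
  ped
}

# Kahn-style topological sort: parents before children.
# Errors naming the individuals on a cycle (a child listed as its own
# ancestor makes the elimination stall).
topological_order <- function(ped) {
  n <- nrow(ped)
  if (n == 0) return(integer(0))
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  placed <- rep(FALSE, n)
  ord <- integer(0)
  repeat {
    ready <- !placed &
      (is.na(fa) | placed[ifelse(is.na(fa), 1L, fa)]) &
      (is.na(mo) | placed[ifelse(is.na(mo), 1L, mo)])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n)
    stop("cycle in parentage involving individual(s): ",
         paste(ped$id[!placed], collapse = ", "))
  ord
}

#' Read a pedigree from a PED/FAM-style file
#'
#' Whitespace-delimited, at least 6 columns:
#' `FamilyID IndividualID FatherID MotherID Sex Phenotyped`, with sex coded
#' 1 = male, 2 = female, 0 = unknown and phenotyped 1/0. The missing-parent
#' marker (default `"0"`) maps to an unknown parent. When
#' `create_missing_parents = TRUE`, a parent id that is referenced but has no
#' row of its own gets an unphenotyped placeholder founder row; otherwise
#' that is an error.
#'
#' @param path path to the file.
#' @param missing_parent string marking an unknown parent (PED convention "0").
#' @param create_missing_parents auto-create placeholder founders for parents
#'   referenced but not listed.
#' @return A [pedigree].
#' @export
read_pedigree <- function(path, missing_parent = "0",
                          create_missing_parents = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#")
  if (ncol(tab) < 6)
    stop("PED file must have at least 6 columns, found ", ncol(tab))
  tab <- tab[, 1:6]
  names(tab) <- c("fid", "id", "father", "mother", "sex_code", "pheno_code")
  tab$father[tab$father == missing_parent] <- NA_character_
  tab$mother[tab$mother == missing_parent] <- NA_character_
  sex <- c("0" = "unknown", "1" = "male", "2" = "female")[tab$sex_code]
  sex[is.na(sex)] <- "unknown"
  ped <- data.frame(
    fid = tab$fid, id = tab$id, father = tab$father, mother = tab$mother,
    sex = unname(sex), phenotyped = tab$pheno_code == "1",
    stringsAsFactors = FALSE
  )
  if (create_missing_parents) {
    for (col in c("father", "mother")) {
      ref <- unique(ped[[col]][!is.na(ped[[col]])])
      absent <- setdiff(ref, ped$id)
      if (length(absent) > 0) {
        rows <- ped[match(absent, ped[[col]]), ]
        ped <- rbind(ped, data.frame(
          fid = rows$fid, id = absent,
          father = NA_character_, mother = NA_character_,
          sex = if (col == "father") "male" else "female",
          phenotyped = FALSE, stringsAsFactors = FALSE
        ))
      }
    }
  }
  validate_pedigree(ped)
}

#' Write a pedigree to a PED/FAM-style file
#'
#' Inverse of [read_pedigree()]: 6 whitespace-delimited columns with sex
#' coded 1/2/0 and the missing-parent marker for unknown parents.
#'
#' @param ped a [pedigree].
#' @param path output path.
#' @param missing_parent marker written for unknown parents.
#' @export
write_pedigree <- function(ped, path, missing_parent = "0") {
  stopifnot(is_pedigree(ped))
  out <- data.frame(
    fid = ped$fid, id = ped$id,
    father = ifelse(is.na(ped$father), missing_parent, ped$father),
    mother = ifelse(is.na(ped$mother), missing_parent, ped$mother),
    sex = c(male = "1", female = "2", unknown = "0")[ped$sex],
    pheno = ifelse(ped$phenotyped, "1", "0")
  )
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Founders of a pedigree
#'
#' @param ped a [pedigree].
#' @return logical vector: both parents unknown.
#' @export
is_founder <- function(ped) is.na(ped$father) & is.na(ped$mother)

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("<pedigree> %d individuals (%d phenotyped) in %d families\n",
              nrow(x), sum(x$phenotyped), length(unique(x$fid))))
  invisible(x)
}
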