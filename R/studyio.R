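#' @keywords internal
"_PACKAGE"

.ETHNICITIES <- c("asian", "caucasian", "indian", "african", "mixed")
.CONTROL_TYPES <- c("healthy", "non_diabetic")
.MATCHINGS <- c("age_and_sex", "age_only", "sex_only", "not_reported")

.STUDY_COLS <- c("study_id", "year", "ethnicity", "control_type", "matching",
                 "n_cases", "n_controls",
                 "case_ref_hom", "case_het", "case_eff_hom",
                 "control_ref_hom", "control_het", "control_eff_hom",
                 "nos_score")

#' Describe a biallelic polymorphism
#'
#' A polymorphism is identified by a free-text name and the two allele
#' symbols.  The *reference* allele is the one whose homozygote acts as the
#' baseline genotype in every contrast (e.g. `aa` in `ab vs. aa`); the
#' *effect* allele is the putative risk or protective allele.
#'
#' @param name free-text label, e.g. `"eNOS 4b/a"`.
#' @param ref_allele symbol of the reference allele (e.g. `"a"`, `"G"`).
#' @param eff_allele symbol of the effect allele (e.g. `"b"`, `"T"`).
#' @return An object of class `"polymorphism"`.
#' @examples
#' polymorphism("eNOS G894T", "G", "T")
#' @export
polymorphism <- function(name, ref_allele, eff_allele) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  ref_allele <- as.character(ref_allele)
  eff_allele <- as.character(eff_allele)
  if (!nzchar(ref_allele) || !nzchar(eff_allele))
    stop("allele symbols must be nonempty", call. = FALSE)
  if (identical(ref_allele, eff_allele))
    stop("reference and effect allele must differ", call. = FALSE)
  structure(list(name = name, ref_allele = ref_allele,
                 eff_allele = eff_allele),
            class = "polymorphism")
}

#' @export
print.polymorphism <- function(x, ...) {
  cat(sprintf("<polymorphism> %s  [ref=%s, eff=%s]\n",
              x$name, x$ref_allele, x$eff_allele))
  invisible(x)
}

#' Assemble a validated study collection
#'
#' Bundles a per-study genotype count table with the polymorphism it
#' genotypes.  Each row of `studies` is one case-control study: identifying
#' label, optional publication year, ethnicity, type of control group,
#' matching scheme, printed sample sizes, the three genotype counts per arm,
#' and a Newcastle-Ottawa quality score (0-10, HWE point included).
#'
#' Published genotype tables are not always internally consistent: the
#' printed sample sizes occasionally disagree with the sum of the printed
#' genotype counts.  With `strict = TRUE` such rows are an error; with
#' `strict = FALSE` they are accepted as-is (the genotype counts drive every
#' statistic, the printed sizes only totals and information accrual).
#'
#' @param studies data.frame with the columns listed above (see
#'   [read_study_table()] for the exact header).
#' @param polymorphism a [polymorphism()] object.
#' @param strict logical; enforce that genotype counts sum to the declared
#'   sample sizes.
#' @return An object of class `"study_dataset"`: a list with elements
#'   `polymorphism` and `studies`.
#' @seealso [read_study_table()], [load_bundled_dataset()], [subset_studies()]
#' @export
study_dataset <- function(studies, polymorphism, strict = TRUE) {
  if (!inherits(polymorphism, "polymorphism"))
    stop("'polymorphism' must be a polymorphism object", call. = FALSE)
  studies <- as.data.frame(studies, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.STUDY_COLS, names(studies))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  studies <- studies[, .STUDY_COLS]
  if (nrow(studies) == 0L)
    stop("a study collection must contain at least one study", call. = FALSE)
  if (anyDuplicated(studies$study_id))
    stop("duplicate study_id: ",
         paste(unique(studies$study_id[duplicated(studies$study_id)]),
               collapse = ", "), call. = FALSE)

  count_cols <- c("n_cases", "n_controls",
                  "case_ref_hom", "case_het", "case_eff_hom",
                  "control_ref_hom", "control_het", "control_eff_hom")
  for (cl in count_cols) {
    v <- studies[[cl]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop(sprintf("column '%s', row %d: counts must be nonnegative integers",
                   cl, bad[1L]), call. = FALSE)
    studies[[cl]] <- as.integer(round(v))
  }
  check_enum <- function(col, levels) {
    bad <- which(!(studies[[col]] %in% levels))
    if (length(bad))
      stop(sprintf("column '%s', row %d: unknown label '%s' (expected %s)",
                   col, bad[1L], studies[[col]][bad[1L]],
                   paste(levels, collapse = "/")), call. = FALSE)
  }
  check_enum("ethnicity", .ETHNICITIES)
  check_enum("control_type", .CONTROL_TYPES)
  check_enum("matching", .MATCHINGS)
  bad_nos <- which(is.na(studies$nos_score) | studies$nos_score < 0 |
                     studies$nos_score > 10)
  if (length(bad_nos))
    stop(sprintf("row %d: nos_score must lie in [0, 10]", bad_nos[1L]),
         call. = FALSE)
  studies$nos_score <- as.integer(round(studies$nos_score))
  studies$year <- as.integer(round(studies$year))
  case_tot <- studies$case_ref_hom + studies$case_het + studies$case_eff_hom
  ctrl_tot <- studies$control_ref_hom + studies$control_het +
    studies$control_eff_hom
  if (any(case_tot == 0L) || any(ctrl_tot == 0L))
    stop("every study needs at least one genotyped subject per arm",
         call. = FALSE)
  if (strict) {
    bad <- which(case_tot != studies$n_cases | ctrl_tot != studies$n_controls)
    if (length(bad))
      stop(sprintf(paste0("row %d (%s): genotype counts sum to %d/%d but ",
                          "n_cases/n_controls declare %d/%d"),
                   bad[1L], studies$study_id[bad[1L]],
                   case_tot[bad[1L]], ctrl_tot[bad[1L]],
                   studies$n_cases[bad[1L]], studies$n_controls[bad[1L]]),
           call. = FALSE)
  }
  rownames(studies) <- NULL
  structure(list(polymorphism = polymorphism, studies = studies),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  s <- x$studies
  cat(sprintf("<study_dataset> %s: %d studies (%s cases / %s controls)\n",
              x$polymorphism$name, nrow(s),
              format(sum(s$n_cases), big.mark = ","),
              format(sum(s$n_controls), big.mark = ",")))
  tab <- table(s$ethnicity)
  cat("  ethnicity:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Number of studies in a collection
#' @param x a `study_dataset`.
#' @return integer study count.
#' @export
n_studies <- function(x) {
  stopifnot(inherits(x, "study_dataset"))
  nrow(x$studies)
}

#' Read a study table from CSV
#'
#' Reads the comma-separated interchange dialect: a header row with columns
#' `study_id, year, ethnicity, control_type, matching, n_cases, n_controls,
#' case_ref_hom, case_het, case_eff_hom, control_ref_hom, control_het,
#' control_eff_hom, nos_score`; counts as plain integers; category labels as
#' lower-case snake-case tokens; empty `year` for unknown.
#'
#' @param path file path.
#' @inheritParams study_dataset
#' @return A [study_dataset()].
#' @export
read_study_table <- function(path, polymorphism, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(.STUDY_COLS, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  num_cols <- c("year", "n_cases", "n_controls",
                "case_ref_hom", "case_het", "case_eff_hom",
                "control_ref_hom", "control_het", "control_eff_hom",
                "nos_score")
  for (cl in num_cols) {
    v <- trimws(raw[[cl]])
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop(sprintf("%s: row %d, column '%s': '%s' is not a number",
                   path, bad[1L], cl, v[bad[1L]]), call. = FALSE)
    raw[[cl]] <- num
  }
  study_dataset(raw, polymorphism, strict = strict)
}

#' Write a study table to CSV
#'
#' Emits the same dialect [read_study_table()] accepts; output is
#' byte-stable for identical input, so `write` then `read` round-trips.
#'
#' @param dataset a [study_dataset()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  utils::write.csv(dataset$studies, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Load a bundled genotype-count dataset
#'
#' Three published genotype-count tables for endothelial nitric oxide
#' synthase (eNOS) polymorphisms in type 2 diabetes case-control studies
#' ship with the package: the 4b/a intron-4 VNTR (36 studies), the G894T
#' missense variant (44 studies) and the T786C promoter variant (13
#' studies).  Split cohorts published under one citation appear as separate
#' studies with `_1`/`_2` suffixes.  The printed per-study sample sizes are
#' kept alongside the genotype counts even where the two disagree in the
#' source; see [study_dataset()].
#'
#' @param which dataset selector: `"4b/a"`, `"G894T"` or `"T786C"`
#'   (case-insensitive; `"4b_a"`/`"4ba"` also accepted).
#' @return A [study_dataset()].
#' @examples
#' ds <- load_bundled_dataset("G894T")
#' n_studies(ds)
#' @export
load_bundled_dataset <- function(which = c("4b/a", "G894T", "T786C")) {
  key <- tolower(gsub("[/_]", "", which[1L]))
  info <- switch(key,
    "4ba"   = list(file = "enos_4b_a.csv",
                   poly = polymorphism("eNOS 4b/a", "a", "b")),
    "g894t" = list(file = "enos_g894t.csv",
                   poly = polymorphism("eNOS G894T", "G", "T")),
    "t786c" = list(file = "enos_t786c.csv",
                   poly = polymorphism("eNOS T786C", "T", "C")),
    stop("unknown bundled dataset: ", which[1L], call. = FALSE))
  path <- system.file("extdata", info$file, package = "snpmeta",
                      mustWork = TRUE)
  read_study_table(path, info$poly, strict = FALSE)
}

#' Subset a study collection
#'
#' Filters studies by a predicate over the study columns, preserving row
#' order.  An empty result is returned (with a message), not an error;
#' pooling functions themselves require at least two studies.
#'
#' @param dataset a [study_dataset()].
#' @param subset logical predicate expression over the study columns,
#'   evaluated like in [base::subset()] (e.g. `ethnicity == "asian"`), or a
#'   logical vector of length `n_studies(dataset)`.
#' @return A `study_dataset` with the matching studies.
#' @examples
#' ds <- load_bundled_dataset("4b/a")
#' n_studies(subset_studies(ds, ethnicity == "asian"))
#' @export
subset_studies <- function(dataset, subset) {
  stopifnot(inherits(dataset, "study_dataset"))
  e <- substitute(subset)
  keep <- eval(e, dataset$studies, parent.frame())
  if (!is.logical(keep) || length(keep) != nrow(dataset$studies))
    stop("'subset' must yield one logical per study", call. = FALSE)
  keep[is.na(keep)] <- FALSE
  out <- dataset
  out$studies <- dataset$studies[keep, , drop = FALSE]
  rownames(out$studies) <- NULL
  if (nrow(out$studies) == 0L)
    message("subset is empty for ", dataset$polymorphism$name)
  out
}

# internal: subset by a precomputed logical vector (no NSE)
subset_studies_lgl <- function(dataset, keep) {
  out <- dataset
  out$studies <- dataset$studies[keep, , drop = FALSE]
  rownames(out$studies) <- NULL
  out
}
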