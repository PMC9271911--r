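#' The five genetic-model contrasts
#'
#' Each genetic model collapses the three genotype categories of a biallelic
#' polymorphism into a 2x2 exposure table (cases/controls x
#' exposed/unexposed):
#'
#' * `hybrid` — heterozygote vs reference homozygote (`ab vs aa`),
#' * `homozygous` — effect homozygote vs reference homozygote (`bb vs aa`),
#' * `dominant` — effect-allele carrier vs reference homozygote
#'   (`ab+bb vs aa`),
#' * `recessive` — effect homozygote vs everything else (`bb vs aa+ab`),
#' * `allele` — chromosome-level contrast of effect vs reference allele
#'   (`2*bb+ab` vs `2*aa+ab` per arm, alleles within a person counted
#'   independently).
#'
#' @return Character vector of the five model names.
#' @export
genetic_models <- function() {
  c("hybrid", "homozygous", "dominant", "recessive", "allele")
}

# internal: vectorized contrast cells for all studies of a dataset
contrast_cells <- function(studies, model) {
  model <- match.arg(model, genetic_models())
  with(studies, switch(model,
    hybrid = data.frame(
      exposed_cases = case_het, unexposed_cases = case_ref_hom,
      exposed_controls = control_het, unexposed_controls = control_ref_hom),
    homozygous = data.frame(
      exposed_cases = case_eff_hom, unexposed_cases = case_ref_hom,
      exposed_controls = control_eff_hom,
      unexposed_controls = control_ref_hom),
    dominant = data.frame(
      exposed_cases = case_het + case_eff_hom, unexposed_cases = case_ref_hom,
      exposed_controls = control_het + control_eff_hom,
      unexposed_controls = control_ref_hom),
    recessive = data.frame(
      exposed_cases = case_eff_hom, unexposed_cases = case_ref_hom + case_het,
      exposed_controls = control_eff_hom,
      unexposed_controls = control_ref_hom + control_het),
    allele = data.frame(
      exposed_cases = 2 * case_eff_hom + case_het,
      unexposed_cases = 2 * case_ref_hom + case_het,
      exposed_controls = 2 * control_eff_hom + control_het,
      unexposed_controls = 2 * control_ref_hom + control_het)))
}

#' Build the 2x2 contrast table of a genetic model for one study
#'
#' Collapses a study's genotype counts into the exposure table of the given
#' genetic model.  A table is *inestimable* when a contrast column (exposed
#' or unexposed) is empty in both arms — such a study carries no information
#' about the contrast and is excluded from pooling rather than corrected.
#'
#' @param study a single-row data.frame with the study columns (one row of
#'   `dataset$studies`), or a `study_dataset` of exactly one study.
#' @param model one of [genetic_models()].
#' @return An object of class `"contrast_table"`: list with the four cells
#'   (`exposed_cases`, `unexposed_cases`, `exposed_controls`,
#'   `unexposed_controls`), `corrected` (continuity correction applied yet?)
#'   and `estimable`.
#' @export
build_contrast <- function(study, model) {
  if (inherits(study, "study_dataset")) study <- study$studies
  stopifnot(is.data.frame(study), nrow(study) == 1L)
  cells <- contrast_cells(study, model)
  new_contrast_table(cells$exposed_cases, cells$unexposed_cases,
                     cells$exposed_controls, cells$unexposed_controls,
                     study_id = study$study_id)
}

new_contrast_table <- function(a, b, c, d, corrected = FALSE,
                               study_id = NA_character_) {
  estimable <- !((a == 0 && c == 0) || (b == 0 && d == 0))
  structure(list(exposed_cases = a, unexposed_cases = b,
                 exposed_controls = c, unexposed_controls = d,
                 corrected = corrected, estimable = estimable,
                 study_id = study_id),
            class = "contrast_table")
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("<contrast_table>%s%s%s\n",
              if (!is.na(x$study_id)) paste0(" ", x$study_id) else "",
              if (x$corrected) " (continuity-corrected)" else "",
              if (!x$estimable) " [inestimable]" else ""))
  m <- matrix(c(x$exposed_cases, x$unexposed_cases,
                x$exposed_controls, x$unexposed_controls),
              2, 2, byrow = TRUE,
              dimnames = list(c("cases", "controls"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Continuity correction for sparse 2x2 tables
#'
#' If any cell of an estimable contrast table is zero, adds `increment`
#' (conventionally 0.5) to *all four* cells; otherwise returns the table
#' unchanged.
#'
#' @param table a [build_contrast()] result with `estimable = TRUE`.
#' @param increment value added to every cell when any cell is zero.
#' @return The (possibly corrected) `contrast_table`.
#' @export
apply_continuity <- function(table, increment = 0.5) {
  stopifnot(inherits(table, "contrast_table"))
  if (!table$estimable)
    stop("continuity correction is undefined for an inestimable table",
         call. = FALSE)
  cells <- c(table$exposed_cases, table$unexposed_cases,
             table$exposed_controls, table$unexposed_controls)
  if (any(cells == 0)) {
    cells <- cells + increment
    new_contrast_table(cells[1L], cells[2L], cells[3L], cells[4L],
                       corrected = TRUE, study_id = table$study_id)
  } else table
}

#' Per-study log odds ratio and standard error
#'
#' Woolf estimator on a (continuity-corrected) 2x2 table:
#' `log OR = log(ad/bc)`, `se = sqrt(1/a + 1/b + 1/c + 1/d)`.
#'
#' @param table an estimable, continuity-corrected [build_contrast()] table
#'   with no remaining zero cell.
#' @return List with `study_id`, `log_or`, `se`.
#' @export
estimate_effect <- function(table) {
  stopifnot(inherits(table, "contrast_table"))
  if (!table$estimable)
    stop("cannot estimate an effect from an inestimable table",
         call. = FALSE)
  cells <- c(table$exposed_cases, table$unexposed_cases,
             table$exposed_controls, table$unexposed_controls)
  if (any(cells == 0))
    stop("zero cell remains; apply_continuity() first", call. = FALSE)
  list(study_id = table$study_id,
       log_or = log(cells[1L] * cells[4L] / (cells[2L] * cells[3L])),
       se = sqrt(sum(1 / cells)))
}

# internal: all studies -> cells + effects under one model.
# Returns list(cells=raw df, cc=corrected df, yi, sei, estimable, corrected)
contrast_effects <- function(studies, model, correction = 0.5) {
  cells <- contrast_cells(studies, model)
  a <- cells$exposed_cases; b <- cells$unexposed_cases
  c_ <- cells$exposed_controls; d <- cells$unexposed_controls
  estimable <- !((a == 0 & c_ == 0) | (b == 0 & d == 0))
  zero <- (a == 0 | b == 0 | c_ == 0 | d == 0) & estimable
  cc <- cells + correction * zero
  yi <- log(cc$exposed_cases * cc$unexposed_controls /
              (cc$unexposed_cases * cc$exposed_controls))
  vi <- 1 / cc$exposed_cases + 1 / cc$unexposed_cases +
    1 / cc$exposed_controls + 1 / cc$unexposed_controls
  list(study_id = studies$study_id, cells = cells, cc = cc,
       yi = yi, sei = sqrt(vi), estimable = estimable, corrected = zero)
}
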