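# Differential-staining candidate selection from an antibody
# tissue-profiling table (Human Protein Atlas style).
#
# Staining levels are the usual four-step ordinal scale
# none < weak < moderate < strong, scored per protein and patient in normal
# glandular tissue and in tumor tissue. Two search directions are supported:
# proteins absent in normal tissue but strongly stained in several tumors
# (up_in_tumor), and the complementary search (down_in_tumor).

STAINING_LEVELS <- c("none", "weak", "moderate", "strong")

#' Selection criteria for differential staining
#'
#' Defaults follow the two searches used for candidate discovery:
#' `up_in_tumor` requires no staining in normal glandular cells and strong
#' staining in at least five tumor patients; `down_in_tumor` requires strong
#' normal staining and at least ten tumor patients with weak or no staining.
#'
#' @param direction `"up_in_tumor"` or `"down_in_tumor"`.
#' @param normal_level_required level every (or any, see `normal_mode`)
#'   normal-tissue record must have.
#' @param tumor_min_patients minimum number of tumor patients whose level
#'   falls in `tumor_level_set`.
#' @param tumor_level_set staining levels that count towards
#'   `tumor_min_patients`.
#' @param normal_mode `"all"` (default): every normal record must be at
#'   `normal_level_required`; `"any"`: at least one.
#' @param min_validation optional minimum antibody validation score; `NULL`
#'   (default) disables the filter.
#' @return a `selection_criteria` object.
#' @export
selection_criteria <- function(direction = c("up_in_tumor", "down_in_tumor"),
                               normal_level_required = NULL,
                               tumor_min_patients = NULL,
                               tumor_level_set = NULL,
                               normal_mode = c("all", "any"),
                               min_validation = NULL) {
  direction <- match.arg(direction)
  normal_mode <- match.arg(normal_mode)
  if (direction == "up_in_tumor") {
    normal_level_required <- normal_level_required %||% "none"
    tumor_min_patients <- tumor_min_patients %||% 5L
    tumor_level_set <- tumor_level_set %||% "strong"
  } else {
    normal_level_required <- normal_level_required %||% "strong"
    tumor_min_patients <- tumor_min_patients %||% 10L
    tumor_level_set <- tumor_level_set %||% c("none", "weak")
  }
  stopifnot_scalar_count(tumor_min_patients, "tumor_min_patients", min = 1)
  stopifnot(normal_level_required %in% STAINING_LEVELS,
            all(tumor_level_set %in% STAINING_LEVELS))
  structure(list(direction = direction,
                 normal_level_required = normal_level_required,
                 tumor_min_patients = as.integer(tumor_min_patients),
                 tumor_level_set = tumor_level_set,
                 normal_mode = normal_mode,
                 min_validation = min_validation),
            class = "selection_criteria")
}

validate_staining <- function(records) {
  need <- c("protein_id", "tissue", "patient_id", "level")
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("staining record table must be a non-empty data.frame", call. = FALSE)
  }
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("staining table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(records$level %in% STAINING_LEVELS)) {
    stop("staining level outside {", paste(STAINING_LEVELS, collapse = ", "), "}",
         call. = FALSE)
  }
  if (!all(records$tissue %in% c("normal_glandular", "tumor"))) {
    stop("tissue must be 'normal_glandular' or 'tumor'", call. = FALSE)
  }
  key <- paste(records$protein_id, records$tissue, records$patient_id)
  if (anyDuplicated(key)) {
    stop("duplicate (protein, tissue, patient) staining record", call. = FALSE)
  }
  invisible(records)
}

#' Select candidate proteins by differential staining
#'
#' A protein is selected when its normal-tissue records satisfy the required
#' level (under `normal_mode`) and at least `tumor_min_patients` of its tumor
#' records have a level in `tumor_level_set`. Proteins with tumor records
#' but no normal-tissue records cannot be judged and are excluded with a
#' warning.
#'
#' @param records staining table: data.frame with columns `protein_id`,
#'   `tissue`, `patient_id`, `level` and optionally `validation_score`.
#' @param criteria a [selection_criteria()] object.
#' @return lexicographically sorted character vector of selected protein ids.
#' @export
select_candidates <- function(records, criteria) {
  validate_staining(records)
  stopifnot(inherits(criteria, "selection_criteria"))
  if (!is.null(criteria$min_validation) &&
      !is.null(records$validation_score)) {
    ok <- stats::aggregate(validation_score ~ protein_id, records, max)
    keep <- ok$protein_id[ok$validation_score >= criteria$min_validation]
    records <- records[records$protein_id %in% keep, , drop = FALSE]
  }
  proteins <- unique(records$protein_id)
  no_normal <- character()
  hit <- vapply(proteins, function(p) {
    r <- records[records$protein_id == p, , drop = FALSE]
    nl <- r$level[r$tissue == "normal_glandular"]
    tl <- r$level[r$tissue == "tumor"]
    if (length(nl) == 0L) {
      no_normal <<- c(no_normal, p)
      return(FALSE)
    }
    normal_ok <- if (criteria$normal_mode == "all") {
      all(nl == criteria$normal_level_required)
    } else {
      any(nl == criteria$normal_level_required)
    }
    normal_ok && sum(tl %in% criteria$tumor_level_set) >= criteria$tumor_min_patients
  }, logical(1))
  if (length(no_normal)) {
    warning("excluded (no normal-tissue records): ",
            paste(sort(no_normal), collapse = ", "), call. = FALSE)
  }
  sort(proteins[hit])
}

#' Merge database-selected proteins with literature additions
#'
#' Union preserving input order: selected proteins first, then literature
#' entries not already selected.
#'
#' @param selected,literature character vectors of protein ids.
#' @return character vector.
#' @export
merge_with_literature <- function(selected, literature) {
  c(unique(selected), setdiff(unique(literature), selected))
}

#' Read / write a staining table
#'
#' TSV with header columns `protein_id`, `tissue`, `patient_id`, `level`,
#' `validation_score`.
#'
#' @param path file path.
#' @return `read_staining_table`: validated data.frame.
#' @export
read_staining_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_staining(df)
  df
}

#' @rdname read_staining_table
#' @param records staining data.frame.
#' @export
write_staining_table <- function(records, path) {
  validate_staining(records)
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
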