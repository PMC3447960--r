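#' Select particles from a model or topology
#'
#' Selections may be given as:
#' * `NULL` — all particles;
#' * a logical vector of length `nrow(df)`;
#' * an integer vector of row indices;
#' * a character expression of `and`-joined clauses over the fields
#'   `chain`, `resid`, `domain` and `species`, e.g.
#'   `"chain A and resid 1:268"`, `"domain coiled_coil"`,
#'   `"species CL"`. Residue clauses accept single indices, `a:b` ranges
#'   and comma-separated lists; other clauses accept comma-separated values.
#'
#' An empty selection is an error unless `allow_empty = TRUE`: silently
#' analysing zero particles is almost always a mistake.
#'
#' @param df data frame with the selectable columns.
#' @param selection selection as described above.
#' @param allow_empty return an empty tibble instead of erroring.
#' @return The selected rows of `df`.
#' @export
select_particles <- function(df, selection = NULL, allow_empty = FALSE) {
  idx <- selection_index(df, selection, allow_empty)
  df[idx, , drop = FALSE]
}

selection_index <- function(df, selection, allow_empty = FALSE) {
  n <- nrow(df)
  if (is.null(selection)) return(seq_len(n))
  if (is.logical(selection)) {
    if (length(selection) != n) abort("logical selection has wrong length")
    idx <- which(selection)
  } else if (is.numeric(selection)) {
    if (any(selection < 1 | selection > n)) abort("selection index out of range")
    idx <- as.integer(selection)
  } else if (is.character(selection)) {
    keep <- rep(TRUE, n)
    clauses <- strsplit(selection, "\\s+and\\s+")[[1]]
    for (cl in clauses) {
      keep <- keep & eval_clause(df, trimws(cl))
    }
    idx <- which(keep)
  } else {
    abort("unsupported selection type")
  }
  if (length(idx) == 0 && !allow_empty) {
    abort("selection matched no particles (use allow_empty = TRUE if intended)")
  }
  idx
}

eval_clause <- function(df, clause) {
  m <- regmatches(clause, regexec("^(chain|resid|domain|species)\\s+(.+)$", clause))[[1]]
  if (length(m) != 3) abort(sprintf("cannot parse selection clause '%s'", clause))
  field <- m[2]; value <- m[3]
  if (!field %in% names(df)) {
    abort(sprintf("selection field '%s' not present in the data", field))
  }
  if (field == "resid") {
    parts <- strsplit(value, ",")[[1]]
    resids <- unlist(lapply(trimws(parts), function(p) {
      if (grepl("^[0-9]+[:-][0-9]+$", p)) {
        ab <- as.integer(strsplit(p, "[:-]")[[1]])
        seq(ab[1], ab[2])
      } else if (grepl("^[0-9]+$", p)) {
        as.integer(p)
      } else {
        abort(sprintf("cannot parse residue range '%s'", p))
      }
    }))
    df[[field]] %in% resids
  } else {
    vals <- trimws(strsplit(value, ",")[[1]])
    df[[field]] %in% vals
  }
}
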