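#' Sibship sizes of the study cohort
#'
#' The reference cohort comprises 210 siblings in 100 families: 91 families
#' with two siblings, 8 with three and 1 with four.
#'
#' @return Integer vector of family sizes (length 100, sum 210).
#' @export
study_family_sizes <- function() {
  c(rep(2L, 91L), rep(3L, 8L), 4L)
}

#' Construct a sibling pedigree
#'
#' Builds a pedigree (subject-to-family map) from a vector of sibship sizes.
#' Subject and family identifiers are derived deterministically from position,
#' so the same specification always yields the same pedigree.
#'
#' @param family_sizes Integer vector, number of siblings per family
#'   (all `>= 1`). Defaults to the study cohort structure
#'   ([study_family_sizes()]).
#' @param family_ids Optional character vector of family identifiers, same
#'   length as `family_sizes`. Defaults to `fam001, fam002, ...`.
#' @return A `pedigree`: a data frame with columns `subject_id` and
#'   `family_id`, one row per subject.
#' @examples
#' ped <- make_pedigree()
#' nrow(ped)                    # 210
#' length(unique(ped$family_id))  # 100
#' @export
make_pedigree <- function(family_sizes = study_family_sizes(),
                          family_ids = NULL) {
  if (length(family_sizes) < 1L || anyNA(family_sizes)) {
    stop("'family_sizes' must be a non-empty vector of family sizes")
  }
  family_sizes <- as.integer(family_sizes)
  if (any(family_sizes < 1L)) {
    stop("invalid pedigree specification: all family sizes must be >= 1")
  }
  n_fam <- length(family_sizes)
  if (is.null(family_ids)) {
    family_ids <- sprintf("fam%03d", seq_len(n_fam))
  }
  if (length(family_ids) != n_fam || anyDuplicated(family_ids)) {
    stop("'family_ids' must be unique and match 'family_sizes' in length")
  }
  fam <- rep(family_ids, times = family_sizes)
  sib <- unlist(lapply(family_sizes, seq_len), use.names = FALSE)
  ped <- data.frame(
    subject_id = paste0(fam, "_sib", sib),
    family_id = fam,
    stringsAsFactors = FALSE
  )
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Enumerate within-family sibling pairs
#'
#' @param ped A [make_pedigree()] pedigree.
#' @return Data frame with columns `subject_a`, `subject_b`, `family_id`;
#'   one row per unordered within-family pair.
#' @export
sib_pairs <- function(ped) {
  stopifnot(is.data.frame(ped), all(c("subject_id", "family_id") %in% names(ped)))
  by_fam <- split(ped$subject_id, ped$family_id)
  out <- lapply(names(by_fam), function(f) {
    ids <- by_fam[[f]]
    if (length(ids) < 2L) return(NULL)
    cmb <- utils::combn(ids, 2L)
    data.frame(subject_a = cmb[1L, ], subject_b = cmb[2L, ],
               family_id = f, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(subject_a = character(), subject_b = character(),
                      family_id = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' @export
print.pedigree <- function(x, ...) {
  sizes <- table(table(x$family_id))
  cat(sprintf("Pedigree: %d subjects in %d families (sibship sizes: %s)\n",
              nrow(x), length(unique(x$family_id)),
              paste(sprintf("%sx%s", sizes, names(sizes)), collapse = ", ")))
  invisible(x)
}
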