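## Declarative code-set registry. The phenotyper never hard-codes a single
## ICD/CPT code: all matching goes through named code sets loaded from a
## user-editable YAML file, with a shipped demo registry. Matching is
## case-insensitive and dot-insensitive ("K57.32" == "K5732"), with optional
## prefix patterns ending in "*".

REQUIRED_CODESETS <- c("diverticulosis_dx", "diverticulitis_dx",
                       "diverticular_any_dx", "abdominal_ct",
                       "lower_gi_endoscopy", "colectomy",
                       "percutaneous_drain", "fistula_repair")

normalize_code <- function(x) {
  toupper(gsub("[.[:space:]]", "", trimws(x)))
}

#' Create a code set
#'
#' @param name Code-set name.
#' @param entries Character vector of `"VOCAB:pattern"` strings, where pattern
#'   is an exact code or a prefix ending in `*` (e.g. `"ICD10CM:K57.2*"`).
#' @return A `codeset` object.
#' @export
codeset <- function(name, entries) {
  if (length(entries) == 0) stop("code set '", name, "' has no entries", call. = FALSE)
  parts <- strsplit(entries, ":", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("code set entries must be 'VOCAB:pattern' strings", call. = FALSE)
  }
  vocab <- toupper(vapply(parts, `[[`, "", 1))
  pattern <- vapply(parts, `[[`, "", 2)
  bad <- !vocab %in% VOCABULARIES
  if (any(bad)) {
    stop("unknown vocabulary '", vocab[bad][1], "' in code set '", name, "'",
         call. = FALSE)
  }
  is_prefix <- endsWith(pattern, "*")
  norm <- normalize_code(sub("\\*$", "", pattern))
  if (any(norm == "")) stop("empty pattern in code set '", name, "'", call. = FALSE)
  structure(list(name = name,
                 entries = tibble(vocabulary = vocab, pattern = pattern,
                                  prefix = is_prefix, norm = norm)),
            class = "codeset")
}

#' Vectorised code-set membership test
#'
#' @param set A `codeset`.
#' @param code Character vector of codes.
#' @param vocabulary Character vector (recycled) of vocabularies.
#' @return Logical vector: `TRUE` where the vocabulary matches an entry and
#'   the code equals an exact entry or starts with a prefix entry, after
#'   trimming, upper-casing and removing dots.
#' @export
code_matches <- function(set, code, vocabulary) {
  stopifnot(inherits(set, "codeset"))
  n <- max(length(code), length(vocabulary))
  code <- rep_len(code, n)
  vocabulary <- rep_len(toupper(vocabulary), n)
  norm <- normalize_code(code)
  out <- rep(FALSE, n)
  e <- set$entries
  for (i in seq_len(nrow(e))) {
    hit <- vocabulary == e$vocabulary[i] &
      (if (e$prefix[i]) startsWith(norm, e$norm[i]) else norm == e$norm[i])
    out <- out | hit
  }
  out
}

#' Test whether clinical events match a code set
#'
#' @param set A `codeset`.
#' @param events Events tibble with `code` and `vocabulary` columns.
#' @return Logical vector, one element per event row.
#' @export
event_matches <- function(set, events) {
  if (nrow(events) == 0) return(logical(0))
  code_matches(set, events$code, events$vocabulary)
}

## TRUE when patterns a and b (parsed entry rows) can match a common code.
entries_overlap <- function(a, b) {
  if (a$vocabulary != b$vocabulary) return(FALSE)
  if (!a$prefix && !b$prefix) return(a$norm == b$norm)
  if (a$prefix && !b$prefix) return(startsWith(b$norm, a$norm))
  if (!a$prefix && b$prefix) return(startsWith(a$norm, b$norm))
  startsWith(a$norm, b$norm) || startsWith(b$norm, a$norm)
}

## TRUE when everything entry e can match is also matched by entry a.
entry_covered_by <- function(e, a) {
  if (e$vocabulary != a$vocabulary) return(FALSE)
  if (!a$prefix) return(!e$prefix && e$norm == a$norm)
  startsWith(e$norm, a$norm)
}

validate_codesets <- function(registry) {
  missing_sets <- setdiff(REQUIRED_CODESETS, names(registry))
  if (length(missing_sets) > 0) {
    stop("configuration error: required code set '", missing_sets[1],
         "' is missing", call. = FALSE)
  }
  for (nm in names(registry)) {
    if (nrow(registry[[nm]]$entries) == 0) {
      stop("configuration error: code set '", nm, "' is empty", call. = FALSE)
    }
  }
  ## Severity logic needs a partition of diverticular codes: a code matching
  ## both the diverticulosis and diverticulitis sets is illegal at load time.
  osis <- registry$diverticulosis_dx$entries
  itis <- registry$diverticulitis_dx$entries
  for (i in seq_len(nrow(osis))) {
    for (j in seq_len(nrow(itis))) {
      if (entries_overlap(osis[i, ], itis[j, ])) {
        stop("validation error: pattern '", osis$pattern[i],
             "' (diverticulosis_dx) overlaps '", itis$pattern[j],
             "' (diverticulitis_dx)", call. = FALSE)
      }
    }
  }
  ## diverticular_any_dx must cover both sub-sets.
  any_dx <- registry$diverticular_any_dx$entries
  for (sub in c("diverticulosis_dx", "diverticulitis_dx")) {
    ent <- registry[[sub]]$entries
    for (i in seq_len(nrow(ent))) {
      covered <- any(vapply(seq_len(nrow(any_dx)), function(j) {
        entry_covered_by(ent[i, ], any_dx[j, ])
      }, logical(1)))
      if (!covered) {
        stop("validation error: entry '", ent$pattern[i], "' of ", sub,
             " is not covered by diverticular_any_dx", call. = FALSE)
      }
    }
  }
  invisible(registry)
}

#' Load a code-set registry from a YAML file
#'
#' The file has one block per set under a top-level `codesets:` key, each a
#' list of `"VOCAB:pattern"` strings. All eight sets referenced by the
#' phenotyper must be present; `diverticular_any_dx` must cover the union of
#' the diverticulosis and diverticulitis sets, and those two sets must not
#' overlap (the severity logic requires a partition).
#'
#' @param path Path to a YAML file; defaults to the demo registry shipped
#'   with the package. The demo ICD lists split the K57.x family into
#'   diverticulosis (the "without mention of diverticulitis" codes) and
#'   diverticulitis (the rest), with the ICD-9 562.10/562.12 versus
#'   562.11/562.13 analogue; its CPT lists for CT/endoscopy/procedures are
#'   illustrative placeholders that institutional users must review.
#' @return A validated `codeset_registry` (named list of `codeset`s).
#' @export
load_codesets <- function(path = system.file("extdata", "codesets.yaml",
                                             package = "divertiphen")) {
  if (!file.exists(path)) stop("code-set file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$codesets)) {
    stop("configuration error: no 'codesets' block in ", path, call. = FALSE)
  }
  registry <- lapply(names(cfg$codesets), function(nm) {
    codeset(nm, unlist(cfg$codesets[[nm]]))
  })
  names(registry) <- names(cfg$codesets)
  class(registry) <- "codeset_registry"
  validate_codesets(registry)
  registry
}

#' The demo code-set registry shipped with the package
#'
#' @return A validated `codeset_registry`.
#' @export
default_codesets <- function() {
  load_codesets()
}
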