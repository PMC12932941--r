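#' Normalize an ICD-10 (or CPT) code for matching
#'
#' Uppercases, strips surrounding whitespace and removes the dot, so that
#' `"g47.33"` and `"G4733"` compare equal. Normalization is idempotent.
#'
#' @param code Character vector of raw codes.
#' @return Character vector of normalized codes.
#' @examples
#' normalize_icd(c("g47.33", " J44.9 "))
#' @export
normalize_icd <- function(code) {
  if (!is.character(code)) {
    stop("`code` must be a character vector", call. = FALSE)
  }
  bad <- is.na(code) | !nzchar(trimws(code))
  if (any(bad)) {
    stop(
      "empty or missing code(s): ",
      paste(utils::head(sprintf("'%s'", code[bad]), 5), collapse = ", "),
      call. = FALSE
    )
  }
  gsub(".", "", toupper(trimws(code)), fixed = TRUE)
}

# Parse one code-set token into its matcher form. Tokens are either a bare
# root ("J40"), a per-category inclusive range ("J41-J41.8"), or an explicit
# all-descendants wildcard ("J09.x"). Category = first three characters.
parse_code_token <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  raw <- trimws(token)
  if (!nzchar(raw)) stop("empty code-set token", call. = FALSE)
  is_icd_root <- function(x) grepl("^[A-Z][0-9]{2}[A-Z0-9]*$", x)
  if (grepl("-", raw, fixed = TRUE)) {
    parts <- strsplit(raw, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("unparseable range token: '", raw, "'", call. = FALSE)
    }
    lo <- normalize_icd(parts[1])
    hi <- normalize_icd(parts[2])
    if (!is_icd_root(lo) || !is_icd_root(hi)) {
      stop("unparseable range token: '", raw, "'", call. = FALSE)
    }
    if (substr(lo, 1, 3) != substr(hi, 1, 3)) {
      stop("range endpoints span categories: '", raw, "'", call. = FALSE)
    }
    if (lo > hi) stop("range is reversed: '", raw, "'", call. = FALSE)
    return(list(kind = "range", low = lo, high = hi, token = raw))
  }
  if (grepl("\\.[xX]$", raw)) {
    root <- normalize_icd(sub("\\.[xX]$", "", raw))
    if (!is_icd_root(root)) {
      stop("unparseable wildcard token: '", raw, "'", call. = FALSE)
    }
    return(list(kind = "root", root = root, token = raw))
  }
  norm <- normalize_icd(raw)
  if (!is_icd_root(norm) && !grepl("^[0-9]{5}$", norm)) {
    stop("unparseable code-set token: '", raw, "'", call. = FALSE)
  }
  list(kind = "root", root = norm, token = raw)
}

#' Build a code set from its tokens
#'
#' A code set is a named collection of tokens in the grammar used by the
#' shipped criterion tables: bare roots cover themselves and all descendants,
#' `"J09.x"` is an explicit all-descendants wildcard, and `"J41-J41.8"` is a
#' per-category inclusive range (it covers `J41`, `J41.0` through `J41.8` and
#' descendants of the upper endpoint, but not `J41.9`). Tokens that do not
#' parse raise an error at construction time, never at match time.
#'
#' @param tokens Character vector of tokens.
#' @param name Optional set name (used in messages and printing).
#' @return An object of class `code_set`.
#' @examples
#' cs <- code_set(c("J40", "J41-J41.8", "J09.x"), name = "demo")
#' code_matches(c("J41.3", "J41.9"), cs)
#' @export
code_set <- function(tokens, name = "code_set") {
  parsed <- lapply(tokens, parse_code_token)
  structure(
    list(name = name, tokens = tokens, parsed = parsed),
    class = "code_set"
  )
}

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set> ", x$name, ": ", paste(x$tokens, collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Test codes for membership in a code set
#'
#' A (normalized) code matches when it equals a bare root, is a descendant of
#' a root or wildcard root (the root is a prefix), or falls inside an
#' inclusive range: same three-character category, at or above the lower
#' endpoint, and at or below the upper endpoint or a descendant of it, under
#' lexicographic comparison of dot-stripped codes. Matching is deterministic
#' and case-insensitive.
#'
#' @param code Character vector of raw codes.
#' @param set A [code_set()].
#' @return Logical vector, one element per code.
#' @export
code_matches <- function(code, set) {
  stopifnot(inherits(set, "code_set"))
  n <- normalize_icd(code)
  hit <- rep(FALSE, length(n))
  for (tok in set$parsed) {
    hit <- hit | if (tok$kind == "root") {
      n == tok$root | startsWith(n, tok$root)
    } else {
      substr(n, 1, 3) == substr(tok$low, 1, 3) &
        n >= tok$low &
        (n <= tok$high | startsWith(n, tok$high))
    }
  }
  hit
}

#' Load the shipped criterion code sets
#'
#' Reads the versioned code-set resource bundled with the package (or another
#' file in the same format) and returns parsed [code_set()] objects for the
#' diagnosis criteria plus the CPT set used by the surgical-site rule.
#'
#' @param path Path to a code-set YAML file; defaults to the shipped resource.
#' @return A list with elements `version`, `icd` (named list of `code_set`),
#'   and `cpt` (named list of `code_set`).
#' @export
load_code_sets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "code_sets.yaml", package = "periscreen")
  }
  raw <- yaml::read_yaml(path)
  mk <- function(defs) {
    out <- lapply(names(defs), function(nm) {
      code_set(unlist(defs[[nm]]$tokens), name = nm)
    })
    stats::setNames(out, names(defs))
  }
  list(
    version = raw$version,
    icd = mk(raw$code_sets),
    cpt = mk(raw$cpt_sets)
  )
}
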