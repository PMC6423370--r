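# Canonical JSON: a byte-stable serialization used for payload signatures.
# Keys are sorted lexicographically (C locale), no insignificant whitespace,
# numbers printed with %.17g (round-trips IEEE doubles, so parse-then-reserialize
# is the identity), raw vectors embedded as base64 strings.

json_escape <- function(s) {
  if (!grepl('[\\\\"\n\r\t]', s)) return(s)
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub('"', '\\"', s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  s
}

json_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("null")
    if (is.integer(v) || (is.finite(v) && v == round(v) && abs(v) < 2^53)) {
      sprintf("%.0f", v)
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
  out
}

#' Canonical JSON serialization
#'
#' Deterministic JSON used wherever byte stability matters (payload
#' signatures, view documents): object keys sorted, fixed numeric
#' formatting, raw vectors as base64. Serializing the same R structure
#' twice always yields identical bytes, and re-serializing a parsed
#' canonical document reproduces it exactly.
#'
#' @param x an R object: named/unnamed lists, character, numeric, logical,
#'   raw, NULL.
#' @return a length-1 character string of JSON.
#' @export
canonical_json <- function(x) {
  if (is.null(x)) return("null")
  if (is.raw(x)) return(paste0('"', openssl::base64_encode(x), '"'))
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && any(nzchar(nm))) {
      if (any(!nzchar(nm)) || anyDuplicated(nm)) {
        abort("canonical objects need unique, non-empty keys", class = "fm_json_error")
      }
      ord <- order(nm, method = "radix")
      parts <- vapply(ord, function(i) {
        paste0('"', json_escape(nm[i]), '":', canonical_json(x[[i]]))
      }, character(1))
      return(paste0("{", paste(parts, collapse = ","), "}"))
    }
    parts <- vapply(x, canonical_json, character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (length(x) != 1) {
    parts <- vapply(seq_along(x), function(i) canonical_json(x[[i]]), character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (is.character(x)) return(paste0('"', json_escape(x), '"'))
  if (is.logical(x)) return(if (is.na(x)) "null" else if (x) "true" else "false")
  if (is.numeric(x)) return(json_num(x))
  abort(paste0("cannot canonicalize type ", typeof(x)), class = "fm_json_error")
}

#' Sign bytes with HMAC-SHA-256
#'
#' @param msg a character string or raw vector to sign.
#' @param key the pre-shared secret (character or raw).
#' @return lowercase hex digest string.
#' @export
fm_hmac <- function(msg, key) {
  if (is.character(msg)) msg <- charToRaw(msg)
  if (is.character(key)) key <- charToRaw(key)
  as.vector(as.character(openssl::sha256(msg, key = key)), "character")
}
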