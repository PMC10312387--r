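#' Inference parameters
#'
#' Constructs a [ColexParams-class] with the conventional defaults for each
#' inference kind: affix inference uses thresholds (2, 2) — shared affix
#' longer than 2 sounds, remainder longer than 2 sounds — while overlap
#' inference uses the stricter (4, 3) to keep chance resemblances down.
#'
#' @param kind `"affix"` or `"overlap"`; picks the default thresholds.
#' @param affixMin,residueMin override the strict thresholds.
#' @param sides index `"prefix"`, `"suffix"` or `"both"` peripheries.
#' @param sameSideOnly for overlap inference, only admit shared substrings
#'   sitting on the same side of both forms.
#' @return A [ColexParams-class] object.
#' @examples
#' colexParams("affix")
#' colexParams("overlap", sameSideOnly = TRUE)
#' @export
colexParams <- function(kind = c("affix", "overlap"), affixMin = NULL,
                        residueMin = NULL, sides = "both", sameSideOnly = FALSE) {
  kind <- match.arg(kind)
  if (is.null(affixMin)) affixMin <- if (kind == "affix") 2L else 4L
  if (is.null(residueMin)) residueMin <- if (kind == "affix") 2L else 3L
  new("ColexParams", affixMin = as.integer(affixMin),
      residueMin = as.integer(residueMin), sides = sides,
      sameSideOnly = isTRUE(sameSideOnly))
}

setMethod("show", "ColexParams", function(object) {
  cat("ColexParams: affix length >", object@affixMin,
      "| remainder length >", object@residueMin,
      "| sides:", object@sides,
      if (object@sameSideOnly) "| same-side only" else "", "\n")
})

.join <- function(tokens) paste(tokens, collapse = " ")

# empty instance table with the canonical column layout
.empty_instances <- function() {
  data.frame(language_id = character(), family = character(),
             concept_a = character(), concept_b = character(),
             form_a = character(), form_b = character(),
             shared = character(), side_a = character(), side_b = character(),
             entry_a = character(), entry_b = character(),
             stringsAsFactors = FALSE)
}

#' Enumerate admissible affix candidates of a sound sequence
#'
#' Lists every prefix and suffix of a token sequence that passes the
#' two-threshold criterion: the affix has more than `affixMin` tokens and the
#' remaining part of the word has more than `residueMin` tokens. These are
#' the keys under which a word is indexed during partial-colexification
#' inference; a word is never its own candidate (the remainder would be 0).
#'
#' @param tokens character vector of sound tokens.
#' @param params a [ColexParams-class]; its `sides` slot restricts the
#'   enumeration.
#' @return data.frame with columns `key` (space-joined affix tokens),
#'   `side` ("prefix"/"suffix"), `length` (tokens), and list-column `affix`.
#' @examples
#' enumerateAffixes(c("h", "a", "n", "t", "ʃ", "uː"), colexParams("affix"))
#' @export
enumerateAffixes <- function(tokens, params = colexParams("affix")) {
  stopifnot(is(params, "ColexParams"))
  n <- length(tokens)
  lo <- params@affixMin + 1L
  hi <- n - params@residueMin - 1L
  empty <- data.frame(key = character(), side = character(), length = integer(),
                      stringsAsFactors = FALSE)
  empty$affix <- list()
  if (hi < lo) return(empty)
  lens <- lo:hi
  out <- list()
  if (params@sides %in% c("prefix", "both")) {
    pref <- lapply(lens, function(L) tokens[seq_len(L)])
    d <- data.frame(key = vapply(pref, .join, ""), side = "prefix",
                    length = lens, stringsAsFactors = FALSE)
    d$affix <- pref
    out <- c(out, list(d))
  }
  if (params@sides %in% c("suffix", "both")) {
    suff <- lapply(lens, function(L) tokens[(n - L + 1L):n])
    d <- data.frame(key = vapply(suff, .join, ""), side = "suffix",
                    length = lens, stringsAsFactors = FALSE)
    d$affix <- suff
    out <- c(out, list(d))
  }
  do.call(rbind, out)
}

# is sequence a a (possibly improper) prefix or suffix of sequence b?
.is_peripheral_part <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la > lb) return(FALSE)
  identical(a, b[seq_len(la)]) || identical(a, b[(lb - la + 1L):lb])
}

.lang_meta <- function(forms) {
  list(language_id = forms$language_id[1L] %||% NA_character_,
       family = forms$family[1L] %||% NA_character_)
}

#' Full colexifications within one language
#'
#' Finds concepts expressed by an identical surface form (compared on the
#' joined sound-token sequence) via a single pass over an associative array
#' keyed by the form. A form expressing k distinct concepts yields all
#' k(k-1)/2 unordered concept pairs, each witnessed by that form.
#'
#' @param forms data.frame of one language's entries, as returned by
#'   [languageForms()].
#' @return data.frame of colexification instances (columns `concept_a`,
#'   `concept_b`, `form_a`, `form_b`, `shared`, `side_a`, `side_b`, ...);
#'   empty when nothing colexifies.
#' @export
fullColexifications <- function(forms) {
  if (!nrow(forms)) return(.empty_instances())
  meta <- .lang_meta(forms)
  keys <- vapply(forms$segments, .join, "")
  rows <- list()
  for (k in unique(keys)) {
    at <- which(keys == k)
    cps <- forms$concept_id[at]
    ucp <- sort(unique(cps), method = "radix")
    if (length(ucp) < 2L) next
    for (i in seq_len(length(ucp) - 1L)) for (j in (i + 1L):length(ucp)) {
      ea <- min(forms$entry_id[at][cps == ucp[i]])
      eb <- min(forms$entry_id[at][cps == ucp[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        language_id = meta$language_id, family = meta$family,
        concept_a = ucp[i], concept_b = ucp[j], form_a = k, form_b = k,
        shared = k, side_a = "whole", side_b = "whole",
        entry_a = ea, entry_b = eb, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_instances())
  canonicalizeInstances(do.call(rbind, rows), directed = FALSE)
}

# build the affix-candidate associative array for a set of forms;
# returns an environment key -> list of list(i, side)
.affix_index <- function(forms, params) {
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(forms))) {
    aff <- enumerateAffixes(forms$segments[[i]], params)
    if (!nrow(aff)) next
    for (r in seq_len(nrow(aff))) {
      k <- aff$key[r]
      idx[[k]] <- c(idx[[k]], list(list(i = i, side = aff$side[r])))
    }
  }
  idx
}

#' Affix colexifications within one language (efficient, two-stage)
#'
#' Stage one fills an associative array with every admissible affix candidate
#' of every form (see [enumerateAffixes()]). Stage two walks the original
#' forms from longest to shortest (ties broken by form string, then concept)
#' and looks each form up verbatim in the array: a hit means the whole word
#' recurs as a prefix or suffix of some longer host word, and one directed
#' instance is emitted per host with a different concept, pointing from the
#' affix word's concept to the host word's concept.
#'
#' @inheritParams fullColexifications
#' @param params a [ColexParams-class], default thresholds (2, 2).
#' @return data.frame of directed instances: `concept_a` (affix word) ->
#'   `concept_b` (host word); `shared` is the affix word's full token
#'   sequence, `side_b` records where it sits in the host.
#' @export
affixColexifications <- function(forms, params = colexParams("affix")) {
  stopifnot(is(params, "ColexParams"))
  if (nrow(forms) < 2L) return(.empty_instances())
  meta <- .lang_meta(forms)
  keys <- vapply(forms$segments, .join, "")
  lens <- lengths(forms$segments)
  idx <- .affix_index(forms, params)
  ord <- order(-lens, forms$form, forms$concept_id, method = "radix")
  rows <- list()
  for (j in ord) {
    hits <- idx[[keys[j]]]
    if (is.null(hits)) next
    for (h in hits) {
      i <- h$i
      if (forms$concept_id[i] == forms$concept_id[j]) next
      rows[[length(rows) + 1L]] <- data.frame(
        language_id = meta$language_id, family = meta$family,
        concept_a = forms$concept_id[j], concept_b = forms$concept_id[i],
        form_a = keys[j], form_b = keys[i],
        shared = keys[j], side_a = "whole", side_b = h$side,
        entry_a = forms$entry_id[j], entry_b = forms$entry_id[i],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_instances())
  canonicalizeInstances(do.call(rbind, rows), directed = TRUE)
}

.side_rank <- function(side_a, side_b) {
  r <- c(prefix = 1L, suffix = 2L)
  (r[side_a] - 1L) * 2L + r[side_b]
}

#' Overlap colexifications within one language (efficient, two-stage)
#'
#' Uses the same affix-candidate array as [affixColexifications()] but, in
#' the second stage, iterates over the array keys themselves, sorted by
#' length in reverse order (ties broken lexicographically). For each key it
#' considers every pair of distinct indexed forms with distinct concepts and
#' emits an instance carrying the shared substring iff the forms are not
#' identical and neither is a prefix or suffix of the other. Each unordered
#' form pair is reported once, at the longest shared admissible substring.
#'
#' @inheritParams fullColexifications
#' @param params a [ColexParams-class], default thresholds (4, 3). With
#'   `sameSideOnly = TRUE` a substring that is e.g. a suffix of one form and
#'   a prefix of the other is rejected.
#' @return data.frame of undirected instances; `shared` is the witnessing
#'   substring and `side_a`/`side_b` record its position in each form.
#' @export
overlapColexifications <- function(forms, params = colexParams("overlap")) {
  stopifnot(is(params, "ColexParams"))
  if (nrow(forms) < 2L) return(.empty_instances())
  meta <- .lang_meta(forms)
  keys <- vapply(forms$segments, .join, "")
  idx <- .affix_index(forms, params)
  allkeys <- ls(idx, sorted = TRUE)
  if (!length(allkeys)) return(.empty_instances())
  klen <- vapply(strsplit(allkeys, " ", fixed = TRUE), length, 0L)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  rows <- list()
  for (k in allkeys[order(-klen, allkeys, method = "radix")]) {
    hits <- idx[[k]]
    if (length(hits) < 2L) next
    hord <- order(forms$entry_id[vapply(hits, `[[`, 0L, "i")],
                  vapply(hits, `[[`, "", "side"), method = "radix")
    hits <- hits[hord]
    cand <- list()
    for (p in seq_len(length(hits) - 1L)) for (q in (p + 1L):length(hits)) {
      i <- hits[[p]]$i; j <- hits[[q]]$i
      if (i == j) next
      if (forms$concept_id[i] == forms$concept_id[j]) next
      if (keys[i] == keys[j]) next  # identical forms: full colexification
      if (.is_peripheral_part(forms$segments[[i]], forms$segments[[j]]) ||
          .is_peripheral_part(forms$segments[[j]], forms$segments[[i]])) next
      si <- hits[[p]]$side; sj <- hits[[q]]$side
      if (params@sameSideOnly && si != sj) next
      # canonical orientation of the unordered pair
      swap <- .pair_gt(forms$concept_id[i], forms$form[i], forms$entry_id[i],
                       forms$concept_id[j], forms$form[j], forms$entry_id[j])
      a <- if (swap) j else i; b <- if (swap) i else j
      sa <- if (swap) sj else si; sb <- if (swap) si else sj
      pk <- paste(forms$entry_id[a], forms$entry_id[b], sep = "\r")
      if (!is.null(seen[[pk]])) next
      rank <- .side_rank(sa, sb)
      if (is.null(cand[[pk]]) || rank < cand[[pk]]$rank) {
        cand[[pk]] <- list(a = a, b = b, sa = sa, sb = sb, rank = rank)
      }
    }
    for (pk in names(cand)) {
      z <- cand[[pk]]
      seen[[pk]] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        language_id = meta$language_id, family = meta$family,
        concept_a = forms$concept_id[z$a], concept_b = forms$concept_id[z$b],
        form_a = keys[z$a], form_b = keys[z$b],
        shared = k, side_a = z$sa, side_b = z$sb,
        entry_a = forms$entry_id[z$a], entry_b = forms$entry_id[z$b],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_instances())
  canonicalizeInstances(do.call(rbind, rows), directed = FALSE)
}

# TRUE if (ca, fa, ea) sorts after (cb, fb, eb) — canonical pair orientation
.pair_gt <- function(ca, fa, ea, cb, fb, eb) {
  if (ca != cb) return(ca > cb)
  if (fa != fb) return(fa > fb)
  ea > eb
}

#' Naive all-pairs partial colexification (reference oracle)
#'
#' Compares every pair of forms of one language directly, applying the same
#' admissibility predicates as the efficient two-stage methods. Quadratic in
#' the number of forms and intended as a correctness oracle: its canonical
#' instance set must be identical to [affixColexifications()] /
#' [overlapColexifications()] on any input.
#'
#' @inheritParams fullColexifications
#' @param params a [ColexParams-class].
#' @param kind `"affix"` or `"overlap"`.
#' @return data.frame of instances, canonicalized.
#' @export
naivePartialColexifications <- function(forms, params = NULL,
                                        kind = c("affix", "overlap")) {
  kind <- match.arg(kind)
  if (is.null(params)) params <- colexParams(kind)
  if (nrow(forms) < 2L) return(.empty_instances())
  if (kind == "affix") .naive_affix(forms, params) else .naive_overlap(forms, params)
}

.naive_affix <- function(forms, params) {
  meta <- .lang_meta(forms)
  keys <- vapply(forms$segments, .join, "")
  lens <- lengths(forms$segments)
  n <- nrow(forms)
  rows <- list()
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    la <- lens[a]; lb <- lens[b]
    if (la <= params@affixMin || lb - la <= params@residueMin) next
    if (forms$concept_id[a] == forms$concept_id[b]) next
    ta <- forms$segments[[a]]; tb <- forms$segments[[b]]
    emit <- function(side) data.frame(
      language_id = meta$language_id, family = meta$family,
      concept_a = forms$concept_id[a], concept_b = forms$concept_id[b],
      form_a = keys[a], form_b = keys[b], shared = keys[a],
      side_a = "whole", side_b = side,
      entry_a = forms$entry_id[a], entry_b = forms$entry_id[b],
      stringsAsFactors = FALSE)
    if (params@sides %in% c("prefix", "both") && identical(ta, tb[seq_len(la)]))
      rows[[length(rows) + 1L]] <- emit("prefix")
    if (params@sides %in% c("suffix", "both") && identical(ta, tb[(lb - la + 1L):lb]))
      rows[[length(rows) + 1L]] <- emit("suffix")
  }
  if (!length(rows)) return(.empty_instances())
  canonicalizeInstances(do.call(rbind, rows), directed = TRUE)
}

.naive_overlap <- function(forms, params) {
  meta <- .lang_meta(forms)
  keys <- vapply(forms$segments, .join, "")
  lens <- lengths(forms$segments)
  n <- nrow(forms)
  combos <- switch(params@sides,
    prefix = list(c("prefix", "prefix")),
    suffix = list(c("suffix", "suffix")),
    both = list(c("prefix", "prefix"), c("prefix", "suffix"),
                c("suffix", "prefix"), c("suffix", "suffix")))
  if (params@sameSideOnly)
    combos <- Filter(function(cc) cc[1] == cc[2], combos)
  periph <- function(tk, side, L) {
    if (side == "prefix") tk[seq_len(L)] else tk[(length(tk) - L + 1L):length(tk)]
  }
  rows <- list()
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    if (forms$concept_id[a] == forms$concept_id[b]) next
    if (keys[a] == keys[b]) next
    ta <- forms$segments[[a]]; tb <- forms$segments[[b]]
    if (.is_peripheral_part(ta, tb) || .is_peripheral_part(tb, ta)) next
    hiL <- min(lens[a] - params@residueMin - 1L, lens[b] - params@residueMin - 1L)
    loL <- params@affixMin + 1L
    if (hiL < loL) next
    best <- NULL
    for (cc in combos) {
      for (L in hiL:loL) {
        pa <- periph(ta, cc[1], L)
        if (!identical(pa, periph(tb, cc[2], L))) next
        key <- .join(pa)
        # canonical orientation before ranking the side combination
        swap <- .pair_gt(forms$concept_id[a], forms$form[a], forms$entry_id[a],
                         forms$concept_id[b], forms$form[b], forms$entry_id[b])
        sa <- if (swap) cc[2] else cc[1]; sb <- if (swap) cc[1] else cc[2]
        rank <- .side_rank(sa, sb)
        better <- is.null(best) || L > best$L ||
          (L == best$L && key < best$key) ||
          (L == best$L && key == best$key && rank < best$rank)
        if (better) best <- list(L = L, key = key, sa = sa, sb = sb, rank = rank)
        break  # longest match for this side combination found
      }
    }
    if (is.null(best)) next
    swap <- .pair_gt(forms$concept_id[a], forms$form[a], forms$entry_id[a],
                     forms$concept_id[b], forms$form[b], forms$entry_id[b])
    ia <- if (swap) b else a; ib <- if (swap) a else b
    rows[[length(rows) + 1L]] <- data.frame(
      language_id = meta$language_id, family = meta$family,
      concept_a = forms$concept_id[ia], concept_b = forms$concept_id[ib],
      form_a = keys[ia], form_b = keys[ib], shared = best$key,
      side_a = best$sa, side_b = best$sb,
      entry_a = forms$entry_id[ia], entry_b = forms$entry_id[ib],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(.empty_instances())
  canonicalizeInstances(do.call(rbind, rows), directed = FALSE)
}

#' Canonicalize an instance table
#'
#' Puts a colexification-instance table into a canonical form so that
#' instance sets can be compared for equality: for undirected kinds the two
#' endpoints of each instance are ordered by (concept, form, entry); rows are
#' then sorted over all columns.
#'
#' @param x instance data.frame.
#' @param directed is the instance set directed (affix kind)?
#' @return the canonicalized data.frame.
#' @export
canonicalizeInstances <- function(x, directed = FALSE) {
  if (!nrow(x)) return(.empty_instances())
  if (!directed) {
    swap <- mapply(.pair_gt, x$concept_a, x$form_a, x$entry_a,
                   x$concept_b, x$form_b, x$entry_b)
    if (any(swap)) {
      tmp <- x[swap, ]
      x[swap, c("concept_a", "form_a", "side_a", "entry_a")] <-
        tmp[, c("concept_b", "form_b", "side_b", "entry_b")]
      x[swap, c("concept_b", "form_b", "side_b", "entry_b")] <-
        tmp[, c("concept_a", "form_a", "side_a", "entry_a")]
    }
  }
  x <- x[do.call(order, c(unname(as.list(x)), method = "radix")), , drop = FALSE]
  rownames(x) <- NULL
  x
}
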