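.default_alphabet <- c("p", "t", "k", "b", "d", "g", "m", "n", "s", "z",
                       "l", "r", "w", "j", "h", "a", "e", "i", "o", "u")

#' Specification for a synthetic multilingual wordlist
#'
#' Describes a lexicon with planted colexification structure. A global
#' "morphological plan" assigns every concept an expression over abstract
#' morphemes — a single root, a root+root compound, or a copy of another
#' concept's expression (a planted full colexification). Every language then
#' realizes the same plan with its own sound material, so the planted concept
#' pairs recur across languages and the aggregation weights are exercised.
#'
#' Roots are drawn with pairwise distinct initial and pairwise distinct final
#' tokens and realized compounds are plain concatenations, which makes the
#' planted relations decidable at generation time; residual chance
#' resemblances are removed by rejection sampling (see [generateWordlist()]).
#'
#' @param n_languages number of languages (default 5).
#' @param n_concepts number of concepts (default 30).
#' @param root_inventory_size abstract morphemes available to the plan
#'   (default 12; must not exceed the alphabet size).
#' @param alphabet sound tokens to build roots from (default: 20 common IPA
#'   segments).
#' @param root_length_range min/max root length in tokens (default c(5, 7);
#'   the minimum of 5 keeps every planted root admissible under the default
#'   overlap thresholds, which demand shared substrings of 5+ sounds).
#' @param compound_probability probability a concept is expressed as a
#'   root+root compound (default 0.4).
#' @param full_colex_probability probability a concept re-uses an earlier
#'   concept's expression verbatim (default 0.1).
#' @param n_families number of language families, assigned round-robin
#'   (default: about one family per two languages).
#' @param seed integer seed.
#' @return validated list of class `"SynthSpec"`.
#' @export
synthSpec <- function(n_languages = 5, n_concepts = 30,
                      root_inventory_size = 12, alphabet = .default_alphabet,
                      root_length_range = c(5L, 7L),
                      compound_probability = 0.4, full_colex_probability = 0.1,
                      n_families = max(1L, ceiling(n_languages / 2)),
                      seed = 42L) {
  stopifnot(n_languages >= 1, n_concepts >= 1, root_inventory_size >= 1,
            length(root_length_range) == 2, root_length_range[1] >= 5,
            root_length_range[1] <= root_length_range[2],
            compound_probability >= 0, compound_probability <= 1,
            full_colex_probability >= 0, full_colex_probability <= 1,
            n_families >= 1)
  if (root_inventory_size > length(alphabet))
    stop("alphabet too small: need at least one distinct initial token per root")
  if (compound_probability > 0 && root_inventory_size < 2)
    stop("compounds need at least 2 roots in the inventory")
  structure(list(n_languages = as.integer(n_languages),
                 n_concepts = as.integer(n_concepts),
                 root_inventory_size = as.integer(root_inventory_size),
                 alphabet = as.character(alphabet),
                 root_length_range = as.integer(root_length_range),
                 compound_probability = compound_probability,
                 full_colex_probability = full_colex_probability,
                 n_families = as.integer(n_families),
                 seed = as.integer(seed)),
            class = "SynthSpec")
}

.pair_df <- function(a = character(), b = character()) {
  data.frame(concept_a = as.character(a), concept_b = as.character(b),
             stringsAsFactors = FALSE)
}

# derive the planted concept-pair sets from the morphological plan
.plan_truth <- function(plan, labels) {
  keyof <- vapply(plan, paste, "", collapse = "+")
  n <- length(plan)
  full <- list(); affix <- list(); overlap <- list()
  single_of <- vapply(seq_len(n), function(i)
    if (length(plan[[i]]) == 1L) plan[[i]] else NA_integer_, 0L)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      # directed: i's whole expression recurs as a part of j's compound
      if (!is.na(single_of[i]) && length(plan[[j]]) == 2L &&
          single_of[i] %in% plan[[j]])
        affix[[length(affix) + 1L]] <- c(labels[i], labels[j])
      if (j <= i) next
      if (keyof[i] == keyof[j])
        full[[length(full) + 1L]] <- c(labels[i], labels[j])
      else if (length(plan[[i]]) == 2L && length(plan[[j]]) == 2L &&
               length(intersect(plan[[i]], plan[[j]])))
        overlap[[length(overlap) + 1L]] <- c(labels[i], labels[j])
    }
  }
  mk <- function(lst) {
    if (!length(lst)) return(.pair_df())
    m <- do.call(rbind, lst)
    d <- .pair_df(m[, 1], m[, 2])
    d[order(d$concept_a, d$concept_b, method = "radix"), , drop = FALSE]
  }
  list(planted_full = mk(full), planted_affix = mk(affix),
       planted_overlap = mk(overlap))
}

.sample_roots <- function(spec) {
  R <- spec$root_inventory_size
  firsts <- sample(spec$alphabet, R)
  lasts <- sample(spec$alphabet, R)
  lens <- sample(seq(spec$root_length_range[1], spec$root_length_range[2]),
                 R, replace = TRUE)
  lapply(seq_len(R), function(r) {
    mid <- if (lens[r] > 2L) sample(spec$alphabet, lens[r] - 2L, replace = TRUE)
           else character()
    c(firsts[r], mid, lasts[r])
  })
}

.inferred_pairs <- function(inst, directed) {
  if (!nrow(inst)) return(.pair_df())
  d <- unique(.pair_df(inst$concept_a, inst$concept_b))
  d[order(d$concept_a, d$concept_b, method = "radix"), , drop = FALSE]
}

.same_pairs <- function(a, b) {
  isTRUE(all.equal(paste(a$concept_a, a$concept_b),
                   paste(b$concept_a, b$concept_b), check.attributes = FALSE)) ||
    (nrow(a) == 0 && nrow(b) == 0)
}

#' Generate a synthetic wordlist with known colexification structure
#'
#' Realizes the morphological plan of a [synthSpec()] in every language and
#' returns the wordlist together with the planted ground truth (the concept
#' pairs that must appear in the full, affix, and overlap networks). Each
#' language's roots are re-sampled (bounded retries) until the naive all-pairs
#' detectors, run at the default thresholds, find exactly the planted
#' relations — i.e. the emitted lexicon is noise-free: no chance
#' resemblances survive.
#'
#' @param spec a [synthSpec()].
#' @param max_retries per-language root resampling attempts before giving up.
#' @return list with elements `wordlist` (a [Wordlist-class]), `truth` (list
#'   of data.frames `planted_full`, `planted_affix` — directed pairs —, and
#'   `planted_overlap`), and `plan` (the concept -> morpheme expressions).
#' @examples
#' gen <- generateWordlist(synthSpec(n_languages = 2, n_concepts = 10, seed = 7))
#' gen$truth$planted_affix
#' @export
generateWordlist <- function(spec, max_retries = 50L) {
  stopifnot(inherits(spec, "SynthSpec"))
  set.seed(spec$seed)
  M <- spec$n_concepts
  labels <- sprintf("C%03d", seq_len(M))
  langs <- sprintf("L%02d", seq_len(spec$n_languages))
  fams <- sprintf("F%02d", ((seq_len(spec$n_languages) - 1L) %% spec$n_families) + 1L)

  # global morphological plan over abstract morphemes; expressions are kept
  # distinct unless a full colexification is planted explicitly, so that
  # full_colex_probability = 0 really means an edgeless full network
  plan <- vector("list", M)
  used <- character()
  for (i in seq_len(M)) {
    cand <- NULL
    for (att in seq_len(200L)) {
      cand <- if (stats::runif(1) < spec$compound_probability)
        sample(spec$root_inventory_size, 2L)
      else sample(spec$root_inventory_size, 1L)
      if (!paste(cand, collapse = "+") %in% used) break
      cand <- NULL
    }
    if (is.null(cand))
      stop("not enough distinct expressions: enlarge root_inventory_size ",
           "or reduce n_concepts")
    plan[[i]] <- cand
    used <- c(used, paste(cand, collapse = "+"))
    if (i > 1L && stats::runif(1) < spec$full_colex_probability)
      plan[[i]] <- plan[[sample(i - 1L, 1L)]]
  }
  truth <- .plan_truth(plan, labels)

  aff_par <- colexParams("affix")
  ovl_par <- colexParams("overlap")
  rows <- list()
  for (l in seq_along(langs)) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      roots <- .sample_roots(spec)
      segs <- lapply(plan, function(expr) unlist(roots[expr]))
      forms <- data.frame(entry_id = sprintf("%s-%04d", langs[l], seq_len(M)),
                          language_id = langs[l], family = fams[l],
                          concept_id = labels,
                          form = vapply(segs, paste, "", collapse = ""),
                          stringsAsFactors = FALSE)
      forms$segments <- segs
      # rejection sampling: accept only if no chance resemblance slips in
      got_a <- .inferred_pairs(.naive_affix(forms, aff_par), TRUE)
      got_o <- .inferred_pairs(.naive_overlap(forms, ovl_par), FALSE)
      if (.same_pairs(got_a, truth$planted_affix) &&
          .same_pairs(got_o, truth$planted_overlap)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not sample collision-free roots for language ",
                  langs[l], " after ", max_retries, " attempts; ",
                  "enlarge the alphabet or shrink the root inventory")
    rows[[l]] <- forms
  }
  e <- do.call(rbind, rows)
  e <- e[order(e$language_id, e$entry_id, method = "radix"), , drop = FALSE]
  rownames(e) <- NULL
  wl <- new("Wordlist", entries = e,
            metadata = list(source = "synthetic", column_map = NULL,
                            tokenizer = "segments", dropped = 0L,
                            spec_seed = spec$seed))
  list(wordlist = wl, truth = truth, plan = plan)
}

#' Inject peripheral homophony into a wordlist
#'
#' Rewrites a random fraction of each language's forms so that they share an
#' identical peripheral token sequence, creating false-positive partial
#' colexification candidates of a controlled length. Used to check that the
#' length thresholds suppress short chance matches (collisions of length
#' <= `affixMin` must never produce edges) while long ones do surface.
#'
#' @param wl a [Wordlist-class].
#' @param homophony_rate fraction of forms per language to rewrite, in
#'   \[0, 1\].
#' @param seed integer seed.
#' @param collision_length length (tokens) of the shared prefix planted on
#'   the rewritten forms (default 2, below the default affix threshold).
#' @return a new [Wordlist-class]; `homophony_rate = 0` returns the input
#'   unchanged.
#' @export
perturbWordlist <- function(wl, homophony_rate, seed = 1L, collision_length = 2L) {
  stopifnot(is(wl, "Wordlist"), homophony_rate >= 0, homophony_rate <= 1,
            collision_length >= 1)
  if (homophony_rate == 0) return(wl)
  set.seed(seed)
  e <- wl@entries
  alphabet <- unique(unlist(e$segments))
  for (lg in unique(e$language_id)) {
    at <- which(e$language_id == lg)
    k <- ceiling(homophony_rate * length(at))
    if (k < 1L) next
    pick <- at[sample(length(at), k)]
    collision <- sample(alphabet, collision_length, replace = TRUE)
    for (i in pick) {
      s <- e$segments[[i]]
      if (length(s) <= collision_length) next
      s[seq_len(collision_length)] <- collision
      e$segments[[i]] <- s
      e$form[i] <- paste(s, collapse = "")
    }
  }
  new("Wordlist", entries = e,
      metadata = c(wl@metadata, list(perturbed = homophony_rate,
                                     collision_length = collision_length)))
}

#' Precision and recall of an inferred network against planted truth
#'
#' Compares the edge set of an inferred [ColexNetwork-class] with a planted
#' concept-pair set (directed comparison for affix networks).
#'
#' @param net a [ColexNetwork-class].
#' @param planted data.frame with columns `concept_a`, `concept_b` (directed
#'   pairs for affix networks, unordered otherwise).
#' @return list with `precision`, `recall`, `n_inferred`, `n_planted`. An
#'   empty inferred (or planted) set gives precision (or recall) 1 by
#'   convention.
#' @export
recoveryScores <- function(net, planted) {
  stopifnot(is(net, "ColexNetwork"))
  et <- edgeTable(net)
  canon <- function(d) {
    if (!nrow(d)) return(character())
    a <- d$concept_a; b <- d$concept_b
    if (net@kind != "affix") {
      swap <- a > b
      tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    }
    unique(paste(a, b, sep = "\r"))
  }
  got <- canon(et); want <- canon(planted)
  list(precision = if (length(got)) mean(got %in% want) else 1,
       recall = if (length(want)) mean(want %in% got) else 1,
       n_inferred = length(got), n_planted = length(want))
}
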