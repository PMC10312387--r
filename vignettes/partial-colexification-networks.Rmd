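---
title: "Inferring full and partial colexification networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring full and partial colexification networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colexnet)
```

## The problem

A multilingual wordlist records, for a fixed set of concepts, how each
concept is expressed in each of many languages. When one language expresses
two concepts with the *same* word form (Yaqui-style homophony or genuine
polysemy), the concepts are said to *colexify*; aggregating such events over
hundreds of languages yields weighted concept networks that are widely used
as proxies for cross-linguistically recurrent semantic relations.

`colexnet` extends this construction to *partial* colexifications, where two
words share surface material without being identical. Words are modelled as
sequences of sound tokens, and two narrow sequence relations are detected:

* **Affix colexification** (directed): the entire form of one word is a
  prefix or suffix — in the computer-science sense — of another word of the
  same language, as German *Hand* recurs in *Handschuh* "glove". The edge
  points from the reused concept (HAND) to the concept of the containing
  word (GLOVE), so out-degree measures how often a concept's words are
  reused as building blocks (*lexical root productivity*) and in-degree how
  often a concept is expressed by morphologically complex words
  (*compoundhood*).
* **Overlap colexification** (undirected): two forms share a substring that
  is peripheral (a prefix or a suffix) in *both*, while neither form
  contains the other and the forms are not identical — the typical signature
  of two compounds built on the same root. The witnessing substring is
  stored on every edge, because unlike the full case the relation is not
  self-evident from the forms.

Unrestricted substring matching within a language produces dense, noisy
graphs: short matches arise by chance and from grammatical markers (gender,
noun class, part-of-speech morphology). The model therefore restricts
matches to word peripheries and gates them with two length thresholds.

## Admissibility thresholds

A candidate affix of a word with $n$ tokens is admitted when

$$ |\text{affix}| > a \quad\text{and}\quad n - |\text{affix}| > r $$

with both inequalities strict. The defaults are $(a, r) = (2, 2)$ for affix
inference — the smallest accepted affix has 3 sounds and its host keeps an
unshared remainder of at least 3 sounds — and the stricter $(4, 3)$ for
overlap inference (shared part of 5+ sounds, remainders of 4+ sounds on both
forms), because two-sided substring sharing is much more exposed to chance
resemblance than whole-word reuse. Both pairs are configurable via
`colexParams()`; the strict ("greater than") reading is applied uniformly to
both kinds. These are length filters only: no attempt is made to decide
whether a shared stretch is a real morpheme.

## Inference by associative arrays

Per language, all three detectors are single- or two-pass constructions over
hash maps rather than all-pairs scans:

1. **Full**: forms are keyed by their joined token sequence; every key whose
   value list contains $k \ge 2$ distinct concepts contributes all
   $k(k-1)/2$ concept pairs.
2. **Affix**: a first pass indexes every admissible prefix and suffix of
   every form. A second pass walks the original forms from longest to
   shortest (ties broken by form string, then concept) and looks each form
   up *verbatim* among the candidates; a hit means the whole word recurs
   peripherally in some host, and one directed instance per distinct-concept
   host is emitted.
3. **Overlap**: the same candidate index is built under the stricter
   thresholds; the second pass iterates over the index keys themselves,
   longest first (ties broken lexicographically). For each key, every pair
   of distinct indexed forms with distinct concepts is admitted unless the
   forms are identical or stand in a part-of relation. Each unordered form
   pair is reported once, at its longest admissible shared substring;
   without this deduplication, nested shorter keys would double-count the
   same pair and inflate edge weights.

A deliberately naive quadratic reference (`naivePartialColexifications()`)
applies the same admissibility predicates pairwise; the test suite asserts
set equality of canonicalized instances between the two routes on
collision-prone random wordlists and on generated lexicons, across
threshold and side configurations.

Two points in the overlap step were genuinely open and are fixed as follows:

* **Side mixing.** The index keys substrings irrespective of side, so a
  stretch that is a suffix of one word and a prefix of the other is found
  and admitted by default; `colexParams(sameSideOnly = TRUE)` restricts
  matches to prefix/prefix and suffix/suffix. The sides are recorded on
  every witness either way.
* **Tie-breaking.** If a pair shares several longest substrings, the
  lexicographically smallest key wins, and within a key the side
  combination is chosen in a fixed order (prefix/prefix, prefix/suffix,
  suffix/prefix, suffix/suffix) after orienting the pair canonically by
  (concept, form, entry). Both routes implement the same rule, which makes
  equality of the two implementations — and byte-identical exports —
  assertable.

## Aggregation and weights

Per-language instances are merged into a concept graph whose nodes cover
*every* attested concept (isolated ones included). Each edge carries

* `weight_forms` — number of witnessing form pairs,
* `weight_languages` — number of distinct languages attesting the pair,
* `weight_families` — number of distinct language families,

so `weight_families <= weight_languages <= weight_forms` always holds; a
validity method enforces it. Family-less input defaults each language to its
own family, keeping the family weight well-defined on toy data. Degree
computations default to `weight_families`, the weight most robust to
family-internal homophony; this is a convention, not a claim about which
weight is "right", and all three (plus unweighted) are available.

## Reading data

`readWordlist()` accepts CLDF-style forms tables (CSV; `ID`, `Language_ID`,
`Parameter_ID`, `Form`, `Segments`) and plain TSV with mappable columns.
Pre-segmented data is the intended input: the `Segments` column is split on
whitespace, morpheme-boundary markers (`+`, `_`) are dropped by default
(they are annotations, not sounds, and would corrupt affix lengths), and
`source/target` slash notation keeps the target. All strings are normalized
to composed Unicode (NFC), since IPA input mixes composed and decomposed
diacritics. Fallback whitespace and per-character tokenizers support
orthographic toys; note that an example like *Hand*/*Schuh*/*Handschuh*
only matches fully under per-character tokenization with lowercasing, which
is why both switches exist. Duplicate (language, concept, form) rows are
dropped by default — they would inflate weights without new evidence — and
synonyms (several distinct forms per concept) all participate in inference.

## The synthetic generator

`generateWordlist(synthSpec(...))` emulates exactly the mechanism the
inference is designed to detect. A global plan assigns each concept an
expression over abstract morphemes: a single root, a two-root compound
(probability `compound_probability`), or a verbatim copy of an earlier
concept's expression (probability `full_colex_probability`). Every language
realizes the same plan with its own roots, so planted concept pairs recur
across languages. The planted truth follows from the plan alone: copies
give full colexifications, single-root words recurring in compounds give
directed affix pairs, compounds sharing a root give overlap pairs.

Roots are sampled with pairwise distinct initial and final tokens, which
provably rules out accidental same-side sharing and accidental part-of
relations between realized forms; residual mixed-side chance matches are
removed by rejection: a language's roots are re-sampled until the naive
detectors find exactly the planted sets. Default root lengths (5–7 tokens)
keep every planted relation admissible under the default thresholds. The
defaults (5 languages, 30 concepts, 12 roots, compounding rate 0.4, copy
rate 0.1) give lexicons in which roughly a third of concepts are
morphologically complex — a rate in the range typologists report for
compound-rich basic vocabularies — while remaining small enough for
exhaustive oracle comparison.

What the generator does *not* emulate: sound change (all realizations of a
root are identical within a language), cognate morphemes with divergent
surface forms, grammatical affixes, morphophonological alternation at
compound boundaries, and realistic phonotactics. Passing the recovery tests
therefore shows the *algorithmic* pipeline is exact, not that real lexicons
are noise-free; on real data the thresholds only bound, not eliminate,
chance matches. `perturbWordlist()` probes that boundary by planting
peripheral collisions of chosen length: collisions of 2 sounds never
surface under the defaults, collisions of 5 do.

## Analysis

`degreeVector()` returns weighted degrees (in-/out- for affix networks),
`compareDegrees()` the Spearman rank correlation over the shared concepts
of two vectors, with average ranks for ties, the large-sample two-sided
p-value, and the exact null distribution when $n \le 10$ without ties.
`extractSubgraph()` induces subgraphs while preserving annotations, and
`detectCommunities()` delegates to the Infomap or label-propagation
implementations in igraph — community detection is an off-the-shelf step
here, not a contribution — seeded for determinism.

## Validation scale and limitations

The shipped tests run the oracle-equivalence property over ten generated
5-language, 50-form wordlists (with injected homophony) plus
collision-prone random wordlists over a 3-letter alphabet, a threshold grid
of $(a, r) \in \{2..5\}^2$, and exact-recovery checks on the generator
defaults; the whole suite completes in well under a minute. These sizes
were chosen because the associative-array and naive routes must agree on
*sets*, so small, collision-dense inputs exercise more corner cases per
form than large natural lexicons.

On a real dataset of a few hundred languages the same functions apply
unchanged; with a large segmented wordlist collection (for example the
segmented Intercontinental Dictionary Series), the expected qualitative
picture is a moderate positive rank correlation between full-colexification
degree and affix out-degree (productive roots also colexify fully) and
between overlap degree and affix in-degree (both measure compoundhood):

```r
# not run: requires an external download
# git clone --depth 1 --branch v0.2 \
#   https://github.com/intercontinental-dictionary-series/ids-segmented
wl   <- readWordlist("ids-segmented/cldf/forms.csv", dialect = "cldf")
full <- buildNetwork(wl, "full")
aff  <- buildNetwork(wl, "affix")
ovl  <- buildNetwork(wl, "overlap")
compareDegrees(degreeVector(full, "undirected"), degreeVector(aff, "out"))
compareDegrees(degreeVector(aff, "in"), degreeVector(ovl, "undirected"))
```

Known limitations: no cognate-aware ("loose") matching — only surface-
identical material counts; no morpheme segmentation, so a shared stretch
need not be a morpheme; no suffix-tree index (the hash-map construction is
ample at wordlist scale); and the quadratic naive route is intended for
verification, not production use.

## A worked example

```{r example}
df <- data.frame(DOCULECT = "German",
                 CONCEPT = c("HAND", "SHOE", "GLOVE"),
                 FORM = c("Hand", "Schuh", "Handschuh"))
wl <- wordlistFromTable(df, tokenizer = "character", lowercase = TRUE)
net <- buildNetwork(wl, "affix")
edgeTable(net)
witnesses(net)[, c("concept_a", "concept_b", "shared", "side_b")]
```
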