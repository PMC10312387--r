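# In-code fixtures: toy wordlists and collision-prone random form tables.

earth_world_table <- function() {
  data.frame(DOCULECT = "German",
             CONCEPT = c("EARTH", "WORLD", "WORLD"),
             FORM = c("Erde", "Erde", "Welt"),
             stringsAsFactors = FALSE)
}

hand_glove_table <- function() {
  data.frame(DOCULECT = "German",
             CONCEPT = c("HAND", "SHOE", "GLOVE"),
             FORM = c("Hand", "Schuh", "Handschuh"),
             stringsAsFactors = FALSE)
}

toy_wordlist <- function(df, ...) {
  wordlistFromTable(df, tokenizer = "character", ...)
}

# one-language form table from concept -> form string (character tokens)
lang_forms <- function(forms, concepts, language = "L1", family = language,
                       lowercase = FALSE) {
  df <- data.frame(DOCULECT = language, FAMILY = family,
                   CONCEPT = concepts, FORM = forms, stringsAsFactors = FALSE)
  wl <- wordlistFromTable(df, tokenizer = "character", lowercase = lowercase,
                          dedup = FALSE)
  languageForms(wl, language)
}

# deliberately collision-prone random wordlist: tiny alphabet, short forms,
# few concepts -> many accidental affix/overlap/full relations
random_wordlist <- function(n_forms = 50, n_languages = 5, seed = 1,
                            alphabet = c("a", "b", "c"), max_len = 9,
                            n_concepts = 12) {
  set.seed(seed)
  langs <- sprintf("L%02d", seq_len(n_languages))
  df <- data.frame(
    ID = sprintf("r%04d", seq_len(n_forms)),
    DOCULECT = sample(langs, n_forms, replace = TRUE),
    CONCEPT = sprintf("C%02d", sample(n_concepts, n_forms, replace = TRUE)),
    FORM = vapply(seq_len(n_forms), function(i)
      paste(sample(alphabet, sample(max_len, 1), replace = TRUE),
            collapse = ""), ""),
    stringsAsFactors = FALSE)
  wordlistFromTable(df, columnMap = c(id = "ID", language = "DOCULECT",
                                      concept = "CONCEPT", form = "FORM"),
                    tokenizer = "character", dedup = FALSE)
}

# strip the witness-bookkeeping columns that may legitimately differ between
# two implementations (entry ids of full-colexification witnesses etc.)
instance_set <- function(x) {
  x[, c("language_id", "concept_a", "concept_b", "form_a", "form_b",
        "shared", "side_a", "side_b")]
}
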