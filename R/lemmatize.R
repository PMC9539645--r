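# Rule-based English lemmatizer: an irregular-form table plus deterministic
# suffix rules for plurals, -ing and -ed forms. Intentionally lightweight --
# it groups the inflected forms that matter for term counting in forum text
# without a full morphological dictionary. Tokens containing digits (e.g.
# pseudo-words in simulated corpora) pass through unchanged.

.irregular_lemmas <- c(
  # be / common auxiliaries
  am = "be", is = "be", are = "be", was = "be", were = "be", been = "be",
  being = "be", has = "have", had = "have", having = "have",
  does = "do", did = "do", done = "do", doing = "do",
  # frequent irregular verbs
  went = "go", gone = "go", goes = "go", going = "go",
  said = "say", says = "say", saying = "say",
  made = "make", making = "make", got = "get", gotten = "get",
  getting = "get", took = "take", taken = "take", taking = "take",
  came = "come", coming = "come", saw = "see", seen = "see",
  knew = "know", known = "know", thought = "think", felt = "feel",
  found = "find", gave = "give", given = "give", giving = "give",
  told = "tell", left = "leave", kept = "keep", met = "meet",
  ran = "run", running = "run", wrote = "write", written = "write",
  writing = "write", spoke = "speak", spoken = "speak",
  heard = "hear", held = "hold", meant = "mean", sat = "sit",
  stood = "stand", lost = "lose", paid = "pay", sent = "send",
  built = "build", spent = "spend", slept = "sleep", woke = "wake",
  began = "begin", begun = "begin", broke = "break", broken = "break",
  chose = "choose", chosen = "choose", ate = "eat", eaten = "eat",
  fell = "fall", fallen = "fall", grew = "grow", grown = "grow",
  # irregular nouns
  children = "child", people = "person", men = "man", women = "woman",
  feet = "foot", teeth = "tooth", mice = "mouse", lives = "life",
  selves = "self", wives = "wife", leaves = "leaf", days = "day",
  better = "good", best = "good", worse = "bad", worst = "bad"
)

.vowels <- c("a", "e", "i", "o", "u")

# undouble a trailing doubled consonant left by -ing/-ed stripping
# (running -> runn -> run); never undouble ll/ss (telling -> tell)
.undouble <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(w)
  last <- substr(w, n, n)
  prev <- substr(w, n - 1L, n - 1L)
  if (last == prev && !last %in% c(.vowels, "l", "s")) {
    return(substr(w, 1L, n - 1L))
  }
  w
}

#' Lemmatize a vector of lowercase tokens
#'
#' Maps inflected English forms to a base lemma via an irregular-form table
#' and suffix rules (plural \code{-s/-es/-ies}, progressive \code{-ing},
#' past \code{-ed}). The rules are deterministic and conservative: short
#' tokens and tokens containing digits are returned unchanged.
#'
#' @param tokens Character vector of lowercase tokens.
#' @return Character vector of lemmas, same length as `tokens`.
#' @export
#' @examples
#' lemmatize(c("cats", "sleeping", "stopped", "babies", "children"))
lemmatize <- function(tokens) {
  vapply(tokens, .lemmatize_one, character(1), USE.NAMES = FALSE)
}

.lemmatize_one <- function(w) {
  if (is.na(w) || w == "") return(w)
  hit <- unname(.irregular_lemmas[w])
  if (!is.na(hit)) return(hit)
  if (grepl("[0-9]", w)) return(w)
  n <- nchar(w)
  # progressive: -ing
  if (n > 5L && endsWith(w, "ing")) {
    stem <- substr(w, 1L, n - 3L)
    return(.undouble(stem))
  }
  # past: -ied -> -y, -ed
  if (n > 4L && endsWith(w, "ied")) {
    return(paste0(substr(w, 1L, n - 3L), "y"))
  }
  if (n > 4L && endsWith(w, "ed") && substr(w, n - 2L, n - 2L) != "e") {
    stem <- substr(w, 1L, n - 2L)
    return(.undouble(stem))
  }
  # plurals: -ies -> -y ; -(s|x|z|ch|sh)es -> drop es ; -s -> drop s
  if (n > 3L && endsWith(w, "ies")) {
    return(paste0(substr(w, 1L, n - 3L), "y"))
  }
  if (n > 3L && endsWith(w, "es")) {
    stem <- substr(w, 1L, n - 2L)
    if (grepl("(s|x|z|ch|sh)$", stem)) return(stem)
    return(substr(w, 1L, n - 1L))  # e.g. houses -> house
  }
  if (n > 2L && endsWith(w, "s") && !endsWith(w, "ss") && !endsWith(w, "us")) {
    return(substr(w, 1L, n - 1L))
  }
  w
}
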