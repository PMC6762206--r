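#' Consonant-vowel syllable inventory with articulatory features
#'
#' Builds the fixed inventory of 19 consonants crossed with the three vowels
#' /a/, /i/, /u/ (57 consonant-vowel syllables), together with a binary
#' articulatory feature table over four groupings:
#'
#' * **major articulator**: lips, coronal tongue, dorsal tongue, other
#'   (total over all consonants);
#' * **constriction location**: bilabial, labiodental, alveolar (defined
#'   only on a consonant subset);
#' * **constriction degree**: stop, fricative, approximant (defined only on
#'   a consonant subset; nasals are excluded);
#' * **vowel**: a, i, u (total).
#'
#' Each syllable has exactly one active feature per grouping for which it is
#' defined, and all-zero features for groupings on which its consonant is
#' undefined. The location and degree groupings back the restricted
#' classification tasks.
#'
#' @return An object of class `syllable_inventory`: a list with elements
#'   `consonants` (19 symbols), `vowels` (`c("a","i","u")`), `cvs` (57
#'   syllable labels such as `"ba"`), `features` (57 x 13 binary matrix with
#'   a `grouping` attribute naming the grouping of each column), and
#'   per-syllable label vectors `consonant`, `vowel`, `articulator`,
#'   `location`, `degree` (the last two are `NA` outside the restricted
#'   tasks).
#' @examples
#' inv <- make_inventory()
#' length(inv$cvs)              # 57
#' table(inv$articulator)
#' @export
make_inventory <- function() {
  cons <- c("b", "p", "m", "f", "v", "w",
            "d", "t", "n", "s", "z", "sh", "th", "l", "r",
            "g", "k", "y", "h")
  vowels <- c("a", "i", "u")

  articulator <- c(b = "lips", p = "lips", m = "lips", f = "lips", v = "lips",
                   w = "lips",
                   d = "coronal", t = "coronal", n = "coronal", s = "coronal",
                   z = "coronal", sh = "coronal", th = "coronal",
                   l = "coronal", r = "coronal",
                   g = "dorsal", k = "dorsal", y = "dorsal",
                   h = "other")
  location <- c(b = "bilabial", p = "bilabial", m = "bilabial",
                f = "labiodental", v = "labiodental",
                d = "alveolar", t = "alveolar", n = "alveolar",
                s = "alveolar", z = "alveolar", l = "alveolar")
  degree <- c(b = "stop", p = "stop", d = "stop", t = "stop",
              g = "stop", k = "stop",
              f = "fricative", v = "fricative", s = "fricative",
              z = "fricative", sh = "fricative", th = "fricative",
              h = "fricative",
              w = "approximant", l = "approximant", r = "approximant",
              y = "approximant")

  cvs <- as.vector(t(outer(cons, vowels, paste0)))
  cv_cons <- rep(cons, each = length(vowels))
  cv_vowel <- rep(vowels, times = length(cons))

  one_hot <- function(labels, levels, prefix) {
    m <- matrix(0L, length(labels), length(levels),
                dimnames = list(NULL, paste(prefix, levels, sep = ".")))
    for (k in seq_along(levels)) m[, k] <- as.integer(labels %in% levels[k])
    m
  }

  art <- articulator[cv_cons]
  loc <- location[cv_cons]
  deg <- degree[cv_cons]

  features <- cbind(
    one_hot(art, c("lips", "coronal", "dorsal", "other"), "articulator"),
    one_hot(loc, c("bilabial", "labiodental", "alveolar"), "location"),
    one_hot(deg, c("stop", "fricative", "approximant"), "degree"),
    one_hot(cv_vowel, vowels, "vowel")
  )
  rownames(features) <- cvs
  attr(features, "grouping") <- rep(
    c("articulator", "location", "degree", "vowel"),
    times = c(4L, 3L, 3L, 3L)
  )

  structure(
    list(consonants = cons, vowels = vowels, cvs = cvs,
         features = features,
         consonant = stats::setNames(cv_cons, cvs),
         vowel = stats::setNames(cv_vowel, cvs),
         articulator = stats::setNames(unname(art), cvs),
         location = stats::setNames(unname(loc), cvs),
         degree = stats::setNames(unname(deg), cvs)),
    class = "syllable_inventory"
  )
}

#' Map syllable labels onto a classification task
#'
#' Translates consonant-vowel labels into the label set of one of the five
#' classification tasks. The `location` and `degree` tasks are restricted:
#' syllables whose consonant lies outside the task return `NA`.
#'
#' @param inventory A [make_inventory()] object.
#' @param task One of `"cv"`, `"consonant"`, `"vowel"`, `"location"`,
#'   `"degree"`.
#' @param labels Character vector of CV labels to map; defaults to the full
#'   inventory.
#' @return Character vector of task labels (`NA` outside a restricted task),
#'   named by the input CV labels.
#' @export
task_labels <- function(inventory, task = c("cv", "consonant", "vowel",
                                            "location", "degree"),
                        labels = inventory$cvs) {
  task <- match.arg(task)
  stopifnot(inherits(inventory, "syllable_inventory"))
  bad <- setdiff(unique(labels), inventory$cvs)
  if (length(bad) > 0) {
    stop("unknown CV labels: ", paste(bad, collapse = ", "))
  }
  out <- switch(task,
    cv = stats::setNames(labels, labels),
    consonant = inventory$consonant[labels],
    vowel = inventory$vowel[labels],
    location = inventory$location[labels],
    degree = inventory$degree[labels]
  )
  names(out) <- labels
  out
}

#' Binary feature matrix for one articulatory grouping
#'
#' @param inventory A [make_inventory()] object.
#' @param grouping One of `"articulator"`, `"location"`, `"degree"`,
#'   `"vowel"`.
#' @param drop_undefined Drop syllables with no active feature in the
#'   grouping (the restricted-task complement). Default `TRUE`.
#' @return Binary matrix, rows = syllables, columns = grouping categories.
#' @export
feature_matrix <- function(inventory,
                           grouping = c("articulator", "location",
                                        "degree", "vowel"),
                           drop_undefined = TRUE) {
  grouping <- match.arg(grouping)
  cols <- attr(inventory$features, "grouping") == grouping
  m <- inventory$features[, cols, drop = FALSE]
  if (drop_undefined) m <- m[rowSums(m) > 0, , drop = FALSE]
  m
}

#' Block-structured articulator engagement map for electrodes
#'
#' Emulates the somatotopic layout of articulator representations across an
#' electrode grid: each articulator dominates a contiguous block of
#' electrodes, with small seeded positive off-block engagement so the map is
#' non-degenerate.
#'
#' @param n_electrodes Number of electrodes (`>= n_articulators`).
#' @param n_articulators Number of articulators (columns), `>= 1`.
#' @param seed Integer seed; identical seeds give identical maps.
#' @param off_block Engagement scale outside the dominant block (default
#'   0.05).
#' @return An `articulator_map`: non-negative matrix
#'   `[n_electrodes x n_articulators]` with entries in `[0, 1]`, each
#'   articulator dominating one contiguous electrode block.
#' @export
make_articulator_map <- function(n_electrodes, n_articulators, seed = 1,
                                 off_block = 0.05) {
  if (n_articulators < 1 || n_electrodes < n_articulators) {
    stop("need n_electrodes >= n_articulators >= 1")
  }
  set.seed(seed)
  blocks <- split(seq_len(n_electrodes),
                  cut(seq_len(n_electrodes), n_articulators, labels = FALSE))
  w <- matrix(stats::runif(n_electrodes * n_articulators, 0, off_block),
              n_electrodes, n_articulators)
  for (a in seq_len(n_articulators)) {
    w[blocks[[a]], a] <- stats::runif(length(blocks[[a]]), 0.8, 1.0)
  }
  colnames(w) <- c("lips", "coronal", "dorsal", "other")[seq_len(n_articulators)]
  structure(w, class = c("articulator_map", "matrix"))
}
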