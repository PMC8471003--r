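#' Construct labels
#'
#' Tissue constructs are stacks of eight 200 um sections (1.6 mm total,
#' comparable to the human atrial free wall) encoded as 8-character binary
#' strings read top to bottom: `"0"` is myocardium, `"1"` is aortic wall
#' (the fibrosis surrogate). `"11110000"` is aorta in the top four layers
#' over myocardium.
#'
#' @param label Character scalar to validate.
#' @return `assert_construct_label()` returns the label invisibly or errors.
#' @name construct_label
NULL

#' @rdname construct_label
#' @export
assert_construct_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !grepl("^[01]{8}$", label)) {
    stop(sprintf("malformed construct label: %s (need 8 characters of 0/1)",
                 deparse(substitute(label))), call. = FALSE)
  }
  invisible(label)
}

label_bits <- function(label) {
  assert_construct_label(label)
  as.integer(strsplit(label, "")[[1]])
}

#' Layer-count (Hamming) distance between two construct labels
#'
#' The number of 200 um layers at which two constructs hold different
#' tissue types. This is the composition-difference metric underlying the
#' proximal-credit rule.
#'
#' @param a,b Construct labels.
#' @return Integer in `[0, 8]`.
#' @export
#' @examples
#' hamming_distance("11000000", "00110000") # 4
hamming_distance <- function(a, b) {
  sum(label_bits(a) != label_bits(b))
}

#' Fibrotic volume fraction of a construct
#'
#' Fraction of the eight layers that are aortic tissue; one section is
#' 12.5% of the construct volume.
#'
#' @param a Construct label.
#' @return Fraction in `[0, 1]`, a multiple of 0.125.
#' @export
#' @examples
#' volume_fraction("11110000") # 0.5
volume_fraction <- function(a) {
  sum(label_bits(a)) / 8
}

default_fibers <- function() paste0("R", 1:5)

# default permuted 50/50 arrangements: block and alternating heterogeneity
default_permuted_classes <- function() {
  c("11110000", "00001111", "11001100", "00110011", "10101010", "01010101")
}

min_pairwise_hamming <- function(classes) {
  n <- length(classes)
  d <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) d <- min(d, hamming_distance(classes[i], classes[j]))
  }
  as.integer(d)
}

#' Define a study design
#'
#' A study design names the set of construct classes to discriminate, the
#' layer-difference threshold granting proximal (half) credit, and the
#' sampling protocol (rebuilds per class, spectra per fiber per rebuild,
#' collection fibers used).
#'
#' Four designs are available:
#' \describe{
#'   \item{binary}{pure myocardium vs pure aorta (2 classes).}
#'   \item{depth}{a 400 um (two-section) aortic inset at four successively
#'     deeper non-overlapping positions, plus the two pure constructs
#'     (6 classes); proximal threshold 4, the layer difference between
#'     adjacent inset positions.}
#'   \item{volume}{fibrotic volume fraction grown one section (12.5%) at a
#'     time from pure myocardium to pure aorta, filling top-down starting
#'     at the second layer (9 classes); proximal threshold 1.}
#'   \item{permuted}{six 50/50 myocardium/aorta arrangements spanning
#'     block and alternating heterogeneity (configurable via `classes`);
#'     proximal threshold = minimum pairwise layer distance of the set.}
#' }
#'
#' @param name One of `"binary"`, `"depth"`, `"volume"`, `"permuted"`.
#' @param classes Optional class-set override (validated construct labels);
#'   mainly intended for the permuted design, whose exact arrangements are
#'   an experimental choice.
#' @param n_rebuilds Construct rebuilds (subjects) per class, >= 2
#'   (default 3).
#' @param spectra_per_fiber_per_rebuild Spectra acquired per collection
#'   fiber from each rebuild (default 10).
#' @param fibers Collection fiber ids used (default `R1`..`R5`).
#' @return An object of class `lss_study_design`.
#' @export
#' @examples
#' study_design("volume")$classes
study_design <- function(name = c("binary", "depth", "volume", "permuted"),
                         classes = NULL, n_rebuilds = 3L,
                         spectra_per_fiber_per_rebuild = 10L,
                         fibers = default_fibers()) {
  name <- match.arg(name)
  if (is.null(classes)) {
    classes <- switch(
      name,
      binary = c("00000000", "11111111"),
      depth = c("11000000", "00110000", "00001100", "00000011",
                "00000000", "11111111"),
      volume = c("00000000", "01000000", "11000000", "11100000",
                 "11110000", "11111000", "11111100", "11111110",
                 "11111111"),
      permuted = default_permuted_classes()
    )
  }
  vapply(classes, assert_construct_label, character(1))
  if (anyDuplicated(classes)) stop("classes must be distinct", call. = FALSE)
  proximal_threshold <- switch(
    name,
    # no pair of the two binary classes ever earns partial credit
    binary = 0L,
    # anchored to the adjacent-inset layer difference, not the global
    # minimum pairwise distance (which the pure constructs would shrink)
    depth = 4L,
    volume = 1L,
    permuted = min_pairwise_hamming(classes)
  )
  # subject-wise hold-out needs at least one rebuild to hold out
  stopifnot(n_rebuilds >= 2, spectra_per_fiber_per_rebuild >= 1,
            all(fibers %in% default_fibers()))
  structure(
    list(
      name = name,
      classes = unname(classes),
      proximal_threshold = proximal_threshold,
      n_rebuilds = as.integer(n_rebuilds),
      spectra_per_fiber_per_rebuild = as.integer(spectra_per_fiber_per_rebuild),
      fibers = fibers
    ),
    class = "lss_study_design"
  )
}

#' @rdname study_design
#' @export
enumerate_study_classes <- function(name, ...) {
  study_design(name, ...)
}

#' @export
print.lss_study_design <- function(x, ...) {
  cat(sprintf(
    "<lss_study_design> %s: %d classes, proximal threshold %d, %d rebuilds x %d spectra/fiber, fibers %s\n",
    x$name, length(x$classes), x$proximal_threshold, x$n_rebuilds,
    x$spectra_per_fiber_per_rebuild, paste(x$fibers, collapse = ",")
  ))
  cat("  classes:", paste(x$classes, collapse = " "), "\n")
  invisible(x)
}

#' Is a misclassification proximal under a study design?
#'
#' A prediction earns proximal (half) credit when it differs from the true
#' class by exactly the minimal inter-class composition difference of the
#' study, counted in layers.
#'
#' @param pred,truth Construct labels, both members of `design$classes`.
#' @param design A [study_design()].
#' @return Logical scalar. Exact matches are correct, not proximal.
#' @export
is_proximal <- function(pred, truth, design) {
  stopifnot(inherits(design, "lss_study_design"))
  if (!pred %in% design$classes || !truth %in% design$classes) {
    stop("labels must belong to the study's class set", call. = FALSE)
  }
  design$proximal_threshold > 0L &&
    pred != truth &&
    hamming_distance(pred, truth) == design$proximal_threshold
}
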