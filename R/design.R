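#' Condition design for one category analysis
#'
#' Builds the default eight-condition design used throughout the pipeline:
#' two object stimuli of one analysis category, each measured in a naive
#' (pre-training, unrecognizable) and a trained (post-training, recognized)
#' state, plus two nonsense stimuli, each measured in two sessions that
#' bracket the training procedure. Object `pre` conditions are acquired in
#' session 1 and `post` conditions in session 2, so the nonsense
#' session-1/session-2 split is the recognition-free control for anything
#' that merely changes between sessions.
#'
#' @param category Analysis category, `"face"` or `"tool"`.
#' @param object_ids Character vector of two object stimulus identifiers.
#' @param nonsense_ids Character vector of two nonsense stimulus identifiers.
#' @return An object of class `condition_design`: a list with elements
#'   `category` and `conditions`, the latter a data.frame with columns
#'   `label`, `stimulus_id`, `stim_class` (`"object"`/`"nonsense"`) and
#'   `state` (`"pre"`/`"post"` for objects, `"s1"`/`"s2"` for nonsense).
#' @export
condition_design <- function(category = c("face", "tool"),
                             object_ids = c("O1", "O2"),
                             nonsense_ids = c("N1", "N2")) {
  category <- match.arg(category)
  if (length(object_ids) != 2L || anyDuplicated(object_ids))
    stop("design requires exactly 2 distinct object stimuli")
  if (length(nonsense_ids) != 2L || anyDuplicated(nonsense_ids))
    stop("design requires exactly 2 distinct nonsense stimuli")
  if (length(intersect(object_ids, nonsense_ids)))
    stop("stimulus ids must be unique within the design")
  conditions <- rbind(
    data.frame(stimulus_id = rep(object_ids, each = 2L),
               stim_class = "object",
               state = rep(c("pre", "post"), 2L),
               stringsAsFactors = FALSE),
    data.frame(stimulus_id = rep(nonsense_ids, each = 2L),
               stim_class = "nonsense",
               state = rep(c("s1", "s2"), 2L),
               stringsAsFactors = FALSE)
  )
  conditions$label <- paste(conditions$stimulus_id, conditions$state, sep = "_")
  conditions <- conditions[, c("label", "stimulus_id", "stim_class", "state")]
  structure(list(category = category, conditions = conditions),
            class = "condition_design")
}

#' @export
print.condition_design <- function(x, ...) {
  cat("<condition_design> category:", x$category, "-",
      nrow(x$conditions), "conditions\n")
  print(x$conditions, row.names = FALSE)
  invisible(x)
}

#' Canonical order of the nine RDM-profile components
#'
#' The component acronyms read: d = different stimuli, s = same stimulus,
#' U = naively unrecognizable (pre) object, R = induced-recognition (post)
#' object, N = nonsense within session, Na = nonsense across sessions.
#' @return Character vector of length 9.
#' @export
profile_components <- function() {
  c("dU", "dR", "dN", "dNa", "sNa", "UN", "RN", "sRU", "dRU")
}

#' Number of RDM entries per profile component
#' @return Named integer vector summing to 28.
#' @export
profile_weights <- function() {
  stats::setNames(c(1L, 1L, 2L, 2L, 2L, 8L, 8L, 2L, 2L), profile_components())
}

classify_pair <- function(a, b) {
  # a, b: one-row slices of the design conditions table
  if (a$stim_class == "nonsense" && b$stim_class == "nonsense") {
    if (a$stimulus_id == b$stimulus_id) return("sNa")
    if (a$state == b$state) return("dN")
    return("dNa")
  }
  if (a$stim_class == "object" && b$stim_class == "object") {
    if (a$state == b$state)
      return(if (a$state == "pre") "dU" else "dR")
    if (a$stimulus_id == b$stimulus_id) return("sRU")
    return("dRU")
  }
  obj <- if (a$stim_class == "object") a else b
  if (obj$state == "pre") "UN" else "RN"
}

#' Enumerate the 28 condition pairs and their profile components
#'
#' All unordered pairs of the eight conditions, each labelled with the
#' profile component its decoding accuracy contributes to. Pairs are
#' returned in canonical order: components in [profile_components()] order,
#' members sorted lexicographically within a component.
#'
#' @param design A [condition_design()].
#' @return Data frame with columns `member_a`, `member_b`, `component`
#'   (factor with the nine component levels); 28 rows.
#' @export
condition_pairs <- function(design) {
  stopifnot(inherits(design, "condition_design"))
  cond <- design$conditions
  if (nrow(cond) != 8L ||
      sum(cond$stim_class == "object") != 4L ||
      sum(cond$stim_class == "nonsense") != 4L)
    stop("design does not match the 2 objects x {pre,post} + 2 nonsense x {s1,s2} template")
  idx <- utils::combn(seq_len(nrow(cond)), 2L)
  pairs <- data.frame(
    member_a = cond$label[idx[1L, ]],
    member_b = cond$label[idx[2L, ]],
    component = vapply(seq_len(ncol(idx)), function(k) {
      classify_pair(cond[idx[1L, k], ], cond[idx[2L, k], ])
    }, character(1L)),
    stringsAsFactors = FALSE
  )
  pairs$component <- factor(pairs$component, levels = profile_components())
  ord <- order(pairs$component, pairs$member_a, pairs$member_b)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Binary model RDM over the canonical condition pairs
#'
#' High dissimilarity (1) for pairs that cross the recognized/unrecognized
#' group boundary — induced-recognition objects against nonsense (RN) and
#' against naively unrecognizable objects (sRU, dRU) — and low dissimilarity
#' (0) within groups, with naively unrecognizable objects grouped together
#' with nonsense images.
#'
#' @param pairs Output of [condition_pairs()].
#' @return Integer vector of length 28 aligned to `pairs`, with exactly 12 ones.
#' @export
model_rdm <- function(pairs) {
  as.integer(pairs$component %in% c("RN", "sRU", "dRU"))
}
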