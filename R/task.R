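#' Task structure: eight states forming two learned sequences
#'
#' Defines the state space of the sequence-learning task: eight stimulus
#' states partitioned into two ordered four-state "structural sequences".
#' Transitions that are adjacent within a structural sequence are the
#' "inferred" (task-relevant) transitions; with two 4-chains there are
#' exactly six of them.
#'
#' @param states Character vector of 8 unique state identifiers.
#' @param sequences List of two ordered 4-vectors of state identifiers that
#'   partition `states`.
#' @return An object of class `task_structure` with elements `states`,
#'   `sequences`, `inferred_pairs` (data frame of ordered from/to pairs) and
#'   `n_states`.
#' @examples
#' task <- task_structure()
#' nrow(task$inferred_pairs)  # 6 forward adjacencies
#' @export
task_structure <- function(states = LETTERS[1:8],
                           sequences = list(states[1:4], states[5:8])) {
  states <- as.character(states)
  if (length(states) != 8L || anyDuplicated(states))
    stop("task requires 8 unique states")
  if (length(sequences) != 2L || any(lengths(sequences) != 4L))
    stop("task requires two ordered 4-state sequences")
  seq_states <- unlist(sequences)
  if (!setequal(seq_states, states) || anyDuplicated(seq_states))
    stop("the two sequences must partition the 8 states")
  pairs <- do.call(rbind, lapply(sequences, function(s) {
    data.frame(from = s[-length(s)], to = s[-1], stringsAsFactors = FALSE)
  }))
  structure(list(states = states, sequences = sequences,
                 inferred_pairs = pairs, n_states = 8L),
            class = "task_structure")
}

#' Canonical ordering of the 64 ordered state pairs
#'
#' All ordered pairs (i, j) over the 8 task states in row-major order,
#' self-pairs included (8 * 8 = 64). This is the canonical transition order
#' used by the replay-evidence, epoching and regression stages.
#'
#' @param task A [task_structure()].
#' @return Data frame with columns `from`, `to` (state labels), `from_idx`,
#'   `to_idx` (1-based state indices) and `inferred` (logical: forward
#'   structural adjacency).
#' @export
canonical_pairs <- function(task) {
  stopifnot(inherits(task, "task_structure"))
  grid <- expand.grid(to_idx = seq_len(task$n_states),
                      from_idx = seq_len(task$n_states))[, 2:1]
  pairs <- data.frame(
    from = task$states[grid$from_idx],
    to = task$states[grid$to_idx],
    from_idx = grid$from_idx,
    to_idx = grid$to_idx,
    stringsAsFactors = FALSE
  )
  key <- paste(pairs$from, pairs$to)
  inf_key <- paste(task$inferred_pairs$from, task$inferred_pairs$to)
  pairs$inferred <- key %in% inf_key
  rownames(pairs) <- NULL
  pairs
}
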