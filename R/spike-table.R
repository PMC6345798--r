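#' Spike table: per-unit spike trains with metadata
#'
#' Container for a population of sorted single units. Spike times are seconds
#' from session start; `cell_class` is an input label (`"principal"` or
#' `"interneuron"`) -- waveform-based classification is upstream of this
#' package.
#'
#' @param spike_times Named list of numeric vectors (one per unit, seconds);
#'   names are unit ids. Times are sorted ascending on construction; duplicate
#'   times within a unit closer than `dup_tol_s` collapse to one spike.
#' @param region Character vector (length 1 or one per unit).
#' @param cell_class Character vector (length 1 or one per unit); each element
#'   must be `"principal"` or `"interneuron"`.
#' @param dup_tol_s Within-unit duplicate-spike tolerance, seconds.
#' @return An object of class `spike_table`: list with `units` (data.frame:
#'   `unit_id`, `region`, `cell_class`, `n_spikes`) and `spikes` (named list).
#' @examples
#' st <- spike_table(list(u1 = c(0.1, 0.2, 0.3)), region = "hpc",
#'                   cell_class = "principal")
#' n_units(st)
#' @export
spike_table <- function(spike_times, region = "unknown",
                        cell_class = "principal", dup_tol_s = 1e-6) {
  if (!is.list(spike_times) || is.null(names(spike_times)) ||
      anyNA(names(spike_times)) || any(names(spike_times) == ""))
    stop("spike_times must be a named list (names = unit ids)")
  ids <- names(spike_times)
  if (anyDuplicated(ids)) stop("unit_id must be unique")
  cell_class <- rep_len(as.character(cell_class), length(ids))
  region <- rep_len(as.character(region), length(ids))
  bad <- setdiff(unique(cell_class), c("principal", "interneuron"))
  if (length(bad))
    stop("unknown cell_class: ", paste(bad, collapse = ", "))
  spikes <- lapply(spike_times, function(t) {
    t <- as.numeric(t)
    if (anyNA(t)) stop("spike times must be numeric and non-missing")
    if (any(t < 0)) stop("spike times must be >= 0")
    t <- sort(t)
    if (length(t) > 1L) t <- t[c(TRUE, diff(t) > dup_tol_s)]
    t
  })
  structure(
    list(
      units = data.frame(
        unit_id = ids, region = region, cell_class = cell_class,
        n_spikes = vapply(spikes, length, integer(1)),
        stringsAsFactors = FALSE, row.names = NULL
      ),
      spikes = spikes
    ),
    class = "spike_table"
  )
}

#' @rdname spike_table
#' @param x Object to test.
#' @export
is_spike_table <- function(x) inherits(x, "spike_table")

#' @rdname spike_table
#' @export
n_units <- function(x) nrow(x$units)

#' Subset a spike table by unit
#'
#' @param x A `spike_table`.
#' @param unit_ids Character vector of unit ids to keep, or a logical/integer
#'   index into `x$units`.
#' @return A `spike_table` with the selected units, original order preserved.
#' @export
subset_units <- function(x, unit_ids) {
  stopifnot(is_spike_table(x))
  if (is.character(unit_ids)) {
    keep <- x$units$unit_id %in% unit_ids
  } else keep <- unit_ids
  spike_table(x$spikes[x$units$unit_id[keep]],
              region = x$units$region[keep],
              cell_class = x$units$cell_class[keep])
}

#' Principal cells of a spike table
#' @param x A `spike_table`.
#' @export
principal_cells <- function(x) subset_units(x, x$units$cell_class == "principal")

#' Interneurons of a spike table
#' @param x A `spike_table`.
#' @export
interneuron_cells <- function(x) subset_units(x, x$units$cell_class == "interneuron")

#' Pooled population spike train
#'
#' All spikes from all units merged and sorted; used by OFF-state detection,
#' where a gap must be silent across the entire recorded population.
#'
#' @param x A `spike_table`.
#' @return Sorted numeric vector.
#' @export
pooled_spikes <- function(x) {
  stopifnot(is_spike_table(x))
  sort(unlist(x$spikes, use.names = FALSE))
}

#' @export
print.spike_table <- function(x, ...) {
  cat(sprintf("<spike_table: %d unit(s), %d spike(s); %d principal, %d interneuron>\n",
              n_units(x), sum(x$units$n_spikes),
              sum(x$units$cell_class == "principal"),
              sum(x$units$cell_class == "interneuron")))
  invisible(x)
}
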