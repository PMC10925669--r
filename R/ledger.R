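#' Instrument-selection accounting ledger
#'
#' Records, stage by stage, how many variants each step of the
#' instrument-selection cascade removed, with the conservation invariant
#' `final_count = initial_count - sum(removed)` enforced at every update.
#'
#' @param initial_count number of variants entering the cascade (after the
#'   significance screen).
#' @return An `instrument_ledger` object.
#' @export
ledger_new <- function(initial_count) {
  initial_count <- as.integer(initial_count)
  stopifnot(length(initial_count) == 1L, !is.na(initial_count),
            initial_count >= 0L)
  structure(list(initial_count = initial_count,
                 stages = data.frame(stage = character(), removed = integer(),
                                     stringsAsFactors = FALSE)),
            class = "instrument_ledger")
}

#' Record one cascade stage in a ledger
#'
#' @param ledger an [ledger_new()] object.
#' @param stage stage name.
#' @param removed number of variants removed at this stage (>= 0, and no
#'   more than currently remain).
#' @return The updated ledger.
#' @export
ledger_add <- function(ledger, stage, removed) {
  stopifnot(inherits(ledger, "instrument_ledger"))
  removed <- as.integer(removed)
  if (is.na(removed) || removed < 0) stop("removed must be a non-negative count")
  if (removed > ledger_final(ledger))
    stop("cannot remove ", removed, " variants; only ",
         ledger_final(ledger), " remain")
  ledger$stages <- rbind(ledger$stages,
                         data.frame(stage = as.character(stage),
                                    removed = removed, stringsAsFactors = FALSE))
  ledger
}

#' Final variant count of a ledger
#' @param ledger an `instrument_ledger`.
#' @return integer: `initial_count - sum(removed)`.
#' @export
ledger_final <- function(ledger) {
  stopifnot(inherits(ledger, "instrument_ledger"))
  ledger$initial_count - sum(ledger$stages$removed)
}

#' @export
as.data.frame.instrument_ledger <- function(x, ...) {
  remaining <- x$initial_count - cumsum(x$stages$removed)
  rbind(data.frame(stage = "initial", removed = 0L, remaining = x$initial_count,
                   stringsAsFactors = FALSE),
        data.frame(stage = x$stages$stage, removed = x$stages$removed,
                   remaining = as.integer(remaining), stringsAsFactors = FALSE))
}

#' Rebuild a ledger from its data-frame form
#' @param x data frame written by `as.data.frame` on a ledger.
#' @return An `instrument_ledger`.
#' @export
as_ledger <- function(x) {
  stopifnot(is.data.frame(x), all(c("stage", "removed") %in% names(x)))
  ini <- x[x$stage == "initial", , drop = FALSE]
  if (nrow(ini) != 1L) stop("data frame lacks the 'initial' row")
  led <- ledger_new(ini$remaining)
  rest <- x[x$stage != "initial", , drop = FALSE]
  for (i in seq_len(nrow(rest)))
    led <- ledger_add(led, rest$stage[i], rest$removed[i])
  led
}

#' @export
print.instrument_ledger <- function(x, ...) {
  cat(sprintf("instrument ledger: %d -> %d variants\n",
              x$initial_count, ledger_final(x)))
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}
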