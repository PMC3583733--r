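# Allelic-state determination: explicit calls first, reference fallback
# otherwise, with optional strand rescue and full provenance tracking.

# obs vs ancestral/mutant -> state in {-1,0,1} plus note
.stateOf <- function(obs, ancestral, mutant, strandRescue) {
  note <- ""
  state <- if (is.na(obs)) -1L
  else if (obs == mutant) 1L
  else if (obs == ancestral) 0L
  else -1L
  if (state == -1L && strandRescue && !is.na(obs)) {
    comp <- .complementBase(obs)
    if (comp == mutant) {
      state <- 1L; note <- paste0("strand rescue: ", obs, " read as ", comp)
    } else if (comp == ancestral) {
      state <- 0L; note <- paste0("strand rescue: ", obs, " read as ", comp)
    }
  }
  if (state == -1L)
    note <- paste0("observed ", if (is.na(obs)) "N" else obs,
                   " matches neither ", ancestral, " nor ", mutant)
  list(state = state, note = note)
}

#' Determine the allelic state of one marker
#'
#' If the profile has a call at the marker's position on the active build,
#' the observed allele is compared against the marker's ancestral and mutant
#' alleles (`provenance = "called"`); otherwise the reference base stands in
#' (`provenance = "reference"`). State 1 means mutant/derived, 0 ancestral,
#' -1 other. With `strandRescue` (default on), an observed base matching
#' neither allele is retried as its complement before being declared
#' "other", because published marker lists do not use one consistent strand;
#' a rescued state carries a note.
#'
#' @param marker one-row marker definition (see [getMarker()]); must be a
#'   non-indel marker with a position on the active build.
#' @param profile a [SnpProfile-class].
#' @param reference a [ReferenceSequence-class] on the same build.
#' @param strandRescue logical.
#' @return data.frame row: `marker`, `state`, `provenance`, `note`.
#' @export
determineState <- function(marker, profile, reference, strandRescue = TRUE) {
  if (isTRUE(marker$is_indel))
    stop("indel markers have no single-base state: ", marker$name)
  pos <- marker[[paste0("pos_", profile@build)]]
  if (is.na(pos))
    stop("marker ", marker$name, " has no position on ", profile@build,
         "; exclude it before state determination")
  call <- callAt(profile, pos)
  if (nrow(call) == 1L) {
    obs <- call$obs_allele
    provenance <- "called"
  } else {
    obs <- baseAt(reference, pos)
    provenance <- "reference"
  }
  s <- .stateOf(obs, marker$ancestral, marker$mutant, strandRescue)
  data.frame(marker = marker$name, state = s$state, provenance = provenance,
             note = s$note, stringsAsFactors = FALSE)
}

#' Resolve the state of every known marker against a profile
#'
#' One state per eligible marker; indel markers, exclusion-listed markers
#' (default `V218` and `MEH2`) and markers without a position on the active
#' build go to the excluded table with a reason. Markers whose reference
#' base equals the mutant allele are legitimate — the reference Y is a
#' composite of several haplogroups — and are scored like any other. Output
#' is sorted by marker name and therefore independent of iteration order.
#'
#' @param markers a [MarkerTable-class].
#' @param profile a [SnpProfile-class].
#' @param reference a [ReferenceSequence-class] on the same build.
#' @param exclusions marker names (canonical or synonyms) to exclude.
#' @param strandRescue see [determineState()].
#' @return a [StatusTable-class].
#' @export
buildStatusTable <- function(markers, profile, reference,
                             exclusions = c("V218", "MEH2"),
                             strandRescue = TRUE) {
  if (profile@build != reference@build)
    stop("profile is on ", profile@build, " but reference on ",
         reference@build)
  df <- markers@markers
  posCol <- paste0("pos_", profile@build)
  exclCanon <- resolveMarker(markers, exclusions)
  exclCanon <- exclCanon[!is.na(exclCanon)]

  reason <- rep(NA_character_, nrow(df))
  reason[df$name %in% exclCanon] <- "exclusion list"
  reason[is.na(reason) & df$is_indel] <- "indel"
  reason[is.na(reason) & is.na(df[[posCol]])] <-
    paste0("no position on ", profile@build)

  eligible <- which(is.na(reason))
  callIdx <- match(df[[posCol]][eligible], profile@calls$position)
  refBase <- baseAt(reference, df[[posCol]][eligible])

  states <- vector("list", length(eligible))
  for (j in seq_along(eligible)) {
    i <- eligible[[j]]
    if (!is.na(callIdx[[j]])) {
      obs <- profile@calls$obs_allele[callIdx[[j]]]
      provenance <- "called"
    } else {
      obs <- refBase[[j]]
      provenance <- "reference"
    }
    s <- .stateOf(obs, df$ancestral[i], df$mutant[i], strandRescue)
    states[[j]] <- data.frame(marker = df$name[i], state = s$state,
                              provenance = provenance, note = s$note,
                              stringsAsFactors = FALSE)
  }
  st <- do.call(rbind, states)
  if (is.null(st))
    st <- data.frame(marker = character(0), state = integer(0),
                     provenance = character(0), note = character(0),
                     stringsAsFactors = FALSE)
  st <- st[order(st$marker), , drop = FALSE]
  rownames(st) <- NULL
  ex <- data.frame(marker = df$name[!is.na(reason)],
                   reason = reason[!is.na(reason)],
                   stringsAsFactors = FALSE)
  ex <- ex[order(ex$marker), , drop = FALSE]
  rownames(ex) <- NULL
  new("StatusTable", states = st, excluded = ex, build = profile@build)
}

#' Scored states of a StatusTable
#' @param states a [StatusTable-class].
#' @return data.frame `marker`, `state`, `provenance`, `note`.
#' @export
statusStates <- function(states) states@states

#' Excluded markers of a StatusTable
#' @param states a [StatusTable-class].
#' @return data.frame `marker`, `reason`.
#' @export
statusExcluded <- function(states) states@excluded

setMethod("show", "StatusTable", function(object) {
  st <- object@states
  cat("StatusTable (", object@build, "): ", nrow(st), " markers scored (",
      sum(st$state == 1L), " mutant, ", sum(st$state == 0L), " ancestral, ",
      sum(st$state == -1L), " other), ", nrow(object@excluded),
      " excluded\n", sep = "")
})
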