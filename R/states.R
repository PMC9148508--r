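# State inventory and decoding topology of the 49-state gene model.
#
# Counting convention for the 49 states:
#   6 forward + 6 reverse codon-periodic match states        = 12
#   6 forward + 6 reverse insertion states                   = 12
#   6 forward + 6 reverse deletion states                    = 12
#   1 noncoding state                                        =  1
#   4 boundary composites (start/stop x strand), each a
#     3-base unit counted base-wise                          = 12
#                                                       total  49
# Deletion states are realised implicitly as skip transitions between match
# periods (M_p -> M_{p+2} consumes one base and advances the codon period by
# one extra position); they are inventory members but occupy no row of the
# dynamic-programming table. Each boundary composite occupies a single
# decoding row that consumes three input positions atomically, so the DP
# works over 29 rows.

# Fixed, documented row order; ties between equal-scoring predecessors are
# broken towards the lowest row index.
.ROW_LABELS <- c(
  "R",
  paste0("M", 1:6, "+"), paste0("I", 1:6, "+"), "S+", "E+",
  paste0("M", 1:6, "-"), paste0("I", 1:6, "-"), "S-", "E-"
)

.ROW_R   <- 1L
.ROW_MF  <- 1L + 1:6        # M1+..M6+
.ROW_IF  <- 7L + 1:6        # I1+..I6+
.ROW_SF  <- 14L             # forward start composite
.ROW_EF  <- 15L             # forward stop composite
.ROW_MR  <- 15L + 1:6       # M1-..M6-
.ROW_IR  <- 21L + 1:6       # I1-..I6-
.ROW_SR  <- 28L             # reverse start composite (right end of a - gene)
.ROW_ER  <- 29L             # reverse stop composite (left end of a - gene)
.N_ROWS  <- 29L

.COMPOSITE_ROWS <- c(.ROW_SF, .ROW_EF, .ROW_SR, .ROW_ER)

# Bases an input position consumes when a row is entered.
.rowConsumes <- function() {
  k <- rep(1L, .N_ROWS)
  k[.COMPOSITE_ROWS] <- 3L
  k
}

.rowStrand <- function() {
  s <- rep("*", .N_ROWS)
  s[c(.ROW_MF, .ROW_IF, .ROW_SF, .ROW_EF)] <- "+"
  s[c(.ROW_MR, .ROW_IR, .ROW_SR, .ROW_ER)] <- "-"
  s
}

.rowPeriod <- function() {
  p <- rep(NA_integer_, .N_ROWS)
  p[.ROW_MF] <- 1:6; p[.ROW_IF] <- 1:6
  p[.ROW_MR] <- 1:6; p[.ROW_IR] <- 1:6
  p
}

.wrap6 <- function(p) ((p - 1L) %% 6L) + 1L

# Incoming arcs per row given log-space macro transitions.  Each element is a
# matrix with columns `from` (row index) and `logw`.  Codon-boundary periods
# (3 and 6) may additionally branch to a stop composite with weight GE; GE is
# a competing branch weight, i.e. the interior {MM, MI, MD} distribution is
# not renormalised at boundary periods (see the methods vignette).
# Attachment costs are split evenly across the two arcs that tie a segment
# into its surroundings, so that segments truncated at a read edge score
# identically in both orientations (exact strand symmetry) while interior
# segments keep their natural total cost:
#   insertion runs: open+close cost MI*IM, half on entry, half on exit;
#   boundary composites: the gene-side weight GE half on each gene-side
#   arc, and the noncoding attachment sqrt(NSF*NER) half on each
#   noncoding-side arc (entry R->composite and exit composite->R).
.incomingArcs <- function(tl) {
  mio <- (tl[["MI"]] + tl[["IM"]]) / 2
  rside <- (tl[["NSF"]] + tl[["NER"]]) / 4
  gside <- tl[["GE"]] / 2
  arcs <- vector("list", .N_ROWS)
  add <- function(row, from, logw) {
    arcs[[row]] <<- rbind(arcs[[row]], cbind(from = from, logw = logw))
  }
  add(.ROW_R, c(.ROW_R, .ROW_EF, .ROW_SR), c(tl[["NN"]], rside, rside))
  for (p in 1:6) {
    pm1 <- .wrap6(p - 1L); pm2 <- .wrap6(p - 2L)
    # forward matches
    from <- c(.ROW_MF[pm1], .ROW_MF[pm2], .ROW_IF[pm1])
    logw <- c(tl[["MM"]], tl[["MD"]], mio)
    if (p == 1L) { from <- c(from, .ROW_SF); logw <- c(logw, gside) }
    add(.ROW_MF[p], from, logw)
    add(.ROW_IF[p], c(.ROW_MF[p], .ROW_IF[p]), c(mio, tl[["II"]]))
    # reverse matches
    from <- c(.ROW_MR[pm1], .ROW_MR[pm2], .ROW_IR[pm1])
    logw <- c(tl[["MM"]], tl[["MD"]], mio)
    if (p == 1L) { from <- c(from, .ROW_ER); logw <- c(logw, gside) }
    add(.ROW_MR[p], from, logw)
    add(.ROW_IR[p], c(.ROW_MR[p], .ROW_IR[p]), c(mio, tl[["II"]]))
  }
  add(.ROW_SF, .ROW_R, rside)
  add(.ROW_EF, c(.ROW_MF[3L], .ROW_MF[6L]), c(gside, gside))
  add(.ROW_SR, c(.ROW_MR[3L], .ROW_MR[6L]), c(gside, gside))
  add(.ROW_ER, .ROW_R, rside)
  lapply(arcs, function(a) a[order(a[, "from"]), , drop = FALSE])
}

# Outgoing arcs, derived from the incoming table (used by the brute-force
# path enumerator).
.outgoingArcs <- function(tl) {
  inc <- .incomingArcs(tl)
  out <- vector("list", .N_ROWS)
  for (to in seq_len(.N_ROWS)) {
    a <- inc[[to]]
    for (k in seq_len(nrow(a))) {
      out[[a[k, "from"]]] <- rbind(out[[a[k, "from"]]],
                                   cbind(to = to, logw = a[k, "logw"]))
    }
  }
  lapply(out, function(a) a[order(a[, "to"]), , drop = FALSE])
}

# Equal prior over every decoding row: reads may begin (and end) in any
# state, because partial genes truncated at read edges are the core use case.
# Composites may start a sequence only as a whole (their first full position
# is 3); entering a composite mid-way is forbidden by the topology.
.logPrior <- function() log(1 / .N_ROWS)

#' StateInventory: the hidden states of the gene model
#'
#' Enumerates the 49 hidden states of the model under the documented
#' counting convention (see source of `R/states.R`): 12 match, 12 insertion
#' and 12 deletion states (six codon periods on each strand), one noncoding
#' state, and four 3-base boundary composites counted base-wise. The 29
#' decoding rows are the states that occupy rows of the Viterbi table;
#' deletion states are implicit skip transitions and boundary composites
#' collapse to one row each.
#'
#' @slot states character vector of the 49 state identifiers.
#' @slot role one of `"match"`, `"insertion"`, `"deletion"`, `"boundary"`,
#'   `"noncoding"` per state.
#' @slot strand `"+"`, `"-"` or `"*"` per state.
#' @slot period codon period 1..6 for gene states, `NA` otherwise.
#' @slot decodingRows labels of the 29 DP rows, in tie-break order.
#' @slot periodicGroups named list partitioning the 36 gene-region states
#'   into the six codon-period classes.
#' @seealso [stateInventory()], [stateCount()]
#' @export
setClass("StateInventory", representation(
  states = "character", role = "character", strand = "character",
  period = "integer", decodingRows = "character", periodicGroups = "list"
))

setValidity("StateInventory", function(object) {
  n <- length(object@states)
  if (length(object@role) != n || length(object@strand) != n ||
      length(object@period) != n)
    return("states, role, strand and period must have equal length")
  if (anyDuplicated(object@states)) return("duplicated state identifiers")
  if (length(object@periodicGroups) != 6L)
    return("periodicGroups must have exactly 6 classes")
  TRUE
})

#' Enumerate the hidden states of a model
#'
#' @param model an [FgsModel-class] (the inventory is a fixed property of the
#'   model topology; the argument asserts that a loaded model is at hand).
#' @return a [StateInventory-class] with 49 states.
#' @examples
#' inv <- stateInventory(defaultModel("complete"))
#' stateCount(inv)           # 49
#' lengths(periodicGroups(inv))
#' @export
stateInventory <- function(model) {
  stopifnot(is(model, "FgsModel"))
  base <- expand.grid(role = c("M", "I", "D"), period = 1:6,
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  geneStates <- sprintf("%s%d%s", base$role, base$period, base$strand)
  comp <- as.vector(outer(c("S+", "E+", "S-", "E-"), 1:3,
                          function(s, i) sprintf("%s.%d", s, i)))
  states <- c(geneStates, "R", comp)
  role <- c(c(M = "match", I = "insertion", D = "deletion")[base$role],
            "noncoding", rep("boundary", 12L))
  strand <- c(base$strand, "*", rep(c("+", "+", "-", "-"), 3L))
  period <- c(base$period, rep(NA_integer_, 13L))
  groups <- lapply(1:6, function(p) geneStates[base$period == p])
  names(groups) <- paste0("period", 1:6)
  new("StateInventory", states = states, role = unname(role),
      strand = strand, period = period,
      decodingRows = .ROW_LABELS, periodicGroups = groups)
}

#' @describeIn stateInventory number of states in the inventory.
#' @param inventory a [StateInventory-class].
#' @export
stateCount <- function(inventory) length(inventory@states)

#' @describeIn stateInventory the codon-period partition of the gene states.
#' @export
periodicGroups <- function(inventory) inventory@periodicGroups

#' @describeIn stateInventory labels of the 29 Viterbi decoding rows.
#' @export
decodingRows <- function(inventory) inventory@decodingRows

setMethod("show", "StateInventory", function(object) {
  cat("StateInventory:", length(object@states), "states,",
      length(object@decodingRows), "decoding rows,",
      length(object@periodicGroups), "periodic groups\n")
  print(table(object@role))
})
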