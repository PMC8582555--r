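#' Compartment topology of a first-order transfer network
#'
#' Defines the compartments and directed transfer edges of a whole-body
#' nanoparticle biokinetic model. Every systemic organ exchanges with the
#' central blood compartment through one organ-to-blood and one
#' blood-to-organ edge; the alimentary tract is a separate acyclic chain of
#' directed edges ending in a terminal `excretion` sink with no outgoing
#' edges.
#'
#' @param systemic character vector of systemic organ names; each gets a
#'   `organ -> blood` and a `blood -> organ` edge.
#' @param alimentary a two-column data frame (`donor`, `receptor`) of
#'   directed alimentary-tract edges, or `NULL` for none.
#' @return An object of class `compartment_topology` with elements
#'   `compartments` (character) and `edges` (data frame with columns
#'   `donor`, `receptor`).
#' @seealso [mouse_topology()] for the packaged whole-body mouse model.
#' @export
#' @examples
#' compartment_topology(systemic = c("liver", "kidneys"))
compartment_topology <- function(systemic = character(), alimentary = NULL) {
  systemic <- as.character(systemic)
  if (anyDuplicated(systemic)) {
    stop("duplicate systemic organ names", call. = FALSE)
  }
  if ("blood" %in% systemic) {
    stop("'blood' is the central compartment, not a systemic organ",
         call. = FALSE)
  }
  edges <- data.frame(donor = character(), receptor = character(),
                      stringsAsFactors = FALSE)
  if (length(systemic)) {
    edges <- rbind(edges,
                   data.frame(donor = systemic, receptor = "blood",
                              stringsAsFactors = FALSE),
                   data.frame(donor = "blood", receptor = systemic,
                              stringsAsFactors = FALSE))
  }
  compartments <- c("blood", systemic)
  if (!is.null(alimentary)) {
    alimentary <- as.data.frame(alimentary)
    if (!all(c("donor", "receptor") %in% names(alimentary))) {
      stop("'alimentary' needs columns donor, receptor", call. = FALSE)
    }
    alimentary <- alimentary[, c("donor", "receptor")]
    alimentary[] <- lapply(alimentary, as.character)
    .check_acyclic(alimentary)
    edges <- rbind(edges, alimentary)
    compartments <- union(compartments,
                          unique(c(alimentary$donor, alimentary$receptor)))
  }
  if (anyDuplicated(paste(edges$donor, edges$receptor, sep = "->"))) {
    stop("duplicate edges in topology", call. = FALSE)
  }
  if ("excretion" %in% edges$donor) {
    stop("'excretion' is a terminal sink and cannot donate", call. = FALSE)
  }
  structure(list(compartments = compartments, edges = edges),
            class = "compartment_topology")
}

.check_acyclic <- function(edges) {
  # Kahn topological sort on the directed edge list
  nodes <- unique(c(edges$donor, edges$receptor))
  remaining <- edges
  repeat {
    if (!nrow(remaining)) return(invisible(TRUE))
    sources <- setdiff(unique(remaining$donor), unique(remaining$receptor))
    if (!length(sources)) {
      stop("alimentary edge set contains a cycle", call. = FALSE)
    }
    remaining <- remaining[!remaining$donor %in% sources, , drop = FALSE]
  }
}

#' @export
print.compartment_topology <- function(x, ...) {
  cat("Compartment topology:", length(x$compartments), "compartments,",
      nrow(x$edges), "directed edges\n")
  cat("  compartments:", paste(x$compartments, collapse = ", "), "\n")
  invisible(x)
}

#' Whole-body mouse biokinetic topology
#'
#' The 15-compartment whole-body model: blood, 13 systemic organs (tumor,
#' liver, spleen, kidneys, colon, stomach, lungs, small intestine, muscle,
#' bone, skin, brain, heart) each exchanging bidirectionally with blood,
#' plus the alimentary chain liver/stomach -> small intestine -> colon ->
#' excretion. Excretion through the gut is the only sink; no urinary
#' pathway is modeled.
#'
#' @return A `compartment_topology` with 15 compartments and 30 edges.
#' @export
#' @examples
#' topo <- mouse_topology()
#' nrow(topo$edges)  # 30
mouse_topology <- function() {
  organs <- c("tumor", "liver", "spleen", "kidneys", "colon", "stomach",
              "lungs", "small_intestine", "muscle", "bone", "skin",
              "brain", "heart")
  alim <- data.frame(
    donor    = c("liver", "stomach", "small_intestine", "colon"),
    receptor = c("small_intestine", "small_intestine", "colon", "excretion"),
    stringsAsFactors = FALSE
  )
  compartment_topology(systemic = organs, alimentary = alim)
}

#' Directed transfer-rate set
#'
#' A set of first-order transfer-rate constants keyed by directed edge
#' (donor, receptor), in 1/h.
#'
#' @param donor,receptor character vectors naming each edge.
#' @param rate_per_h non-negative rate constants (1/h).
#' @return A data frame of class `transfer_rates` with columns `donor`,
#'   `receptor`, `rate_per_h`.
#' @export
#' @examples
#' transfer_rates("liver", "blood", 0.1159)
transfer_rates <- function(donor = character(), receptor = character(),
                           rate_per_h = numeric()) {
  donor <- as.character(donor); receptor <- as.character(receptor)
  rate_per_h <- as.numeric(rate_per_h)
  if (length(donor) != length(receptor) ||
      length(donor) != length(rate_per_h)) {
    stop("donor, receptor, rate_per_h must have equal length", call. = FALSE)
  }
  if (any(!is.finite(rate_per_h)) || any(rate_per_h < 0)) {
    stop("transfer rates must be finite and >= 0", call. = FALSE)
  }
  keys <- paste(donor, receptor, sep = "->")
  if (anyDuplicated(keys)) {
    stop("duplicate edge in transfer rates: ",
         keys[duplicated(keys)][1L], call. = FALSE)
  }
  structure(data.frame(donor = donor, receptor = receptor,
                       rate_per_h = rate_per_h, stringsAsFactors = FALSE),
            class = c("transfer_rates", "data.frame"))
}

edge_keys <- function(x) paste(x$donor, x$receptor, sep = "->")

#' Whole-body mouse transfer rates
#'
#' The packaged transfer-rate table for the mouse whole-body model:
#' systemic exchange rates between each organ and blood plus the four
#' alimentary-tract rates, read from the fixture file shipped in
#' `inst/extdata/mouse_transfer_rates.csv`.
#'
#' @return A `transfer_rates` object with 30 edges.
#' @export
#' @examples
#' rates <- mouse_transfer_rates()
#' subset(rates, donor == "liver")
mouse_transfer_rates <- function() {
  path <- system.file("extdata", "mouse_transfer_rates.csv",
                      package = "npradbio", mustWork = TRUE)
  read_rates(path)
}

#' Build the rate matrix of a first-order compartment model
#'
#' Assembles the square matrix `A` of the linear system `dx/dt = A x` from
#' a topology and its transfer rates: `A[receptor, donor] = k(donor ->
#' receptor)` and each diagonal entry is minus the sum of its compartment's
#' outgoing rates, so every column sums to zero and total amount is
#' conserved (the excretion sink is an explicit compartment).
#'
#' @param topology a [compartment_topology()].
#' @param rates a [transfer_rates()] covering exactly the topology's edges.
#' @return A named square matrix (1/h) over `topology$compartments`.
#' @export
#' @examples
#' topo <- compartment_topology("liver")
#' A <- rate_matrix(topo, transfer_rates(c("liver", "blood"),
#'                                       c("blood", "liver"), c(0.2, 0.1)))
#' colSums(A)  # all zero
rate_matrix <- function(topology, rates) {
  stopifnot(inherits(topology, "compartment_topology"))
  if (!inherits(rates, "transfer_rates")) {
    rates <- transfer_rates(rates$donor, rates$receptor, rates$rate_per_h)
  }
  want <- paste(topology$edges$donor, topology$edges$receptor, sep = "->")
  have <- edge_keys(rates)
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing)) {
    stop("rates missing for edge(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(extra)) {
    stop("rates given for edge(s) not in topology: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  comps <- topology$compartments
  A <- matrix(0, length(comps), length(comps),
              dimnames = list(comps, comps))
  for (i in seq_len(nrow(rates))) {
    A[rates$receptor[i], rates$donor[i]] <-
      A[rates$receptor[i], rates$donor[i]] + rates$rate_per_h[i]
  }
  diag(A) <- 0
  diag(A) <- -colSums(A)
  A
}
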