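#' The fixed wiring of the immune signaling network
#'
#' The model network has five host proteins -- R (receptor), A (activator),
#' I (immunity), U (upstream regulator), D (downstream regulator) -- plus the
#' pathogen P. Eight directed interactions can form during evolution:
#' P activates/inhibits R, R acts on A, A acts on I, U and D, U acts back on
#' R (the potential upstream NFL), D acts back on I (the potential downstream
#' NFL), and I acts on P (clearance). The edge set is immutable during a run.
#'
#' Each edge is written `(target, source)`: `mu[target, source]` is the signed
#' interaction coefficient of the source acting on the target.
#'
#' @return A data frame with columns `target`, `source` and `name`
#'   (`"<target>_<source>"`), one row per directed edge, in the fixed order
#'   used by every other function in the package.
#' @examples
#' signaling_topology()
#' @export
signaling_topology <- function() {
  data.frame(
    target = c("R", "A", "I", "U", "D", "R", "I", "P"),
    source = c("P", "R", "A", "A", "A", "U", "D", "I"),
    name   = c("R_P", "A_R", "I_A", "U_A", "D_A", "R_U", "I_D", "P_I"),
    stringsAsFactors = FALSE
  )
}

#' @rdname signaling_topology
#' @export
edge_names <- function() signaling_topology()$name

#' Host protein labels, in canonical order
#' @return `c("R", "A", "I", "U", "D")`
#' @export
host_proteins <- function() c("R", "A", "I", "U", "D")

#' Protein domain labels, in canonical order
#'
#' Every protein carries three bit domains: `receiver` (read when the protein
#' is the target of an interaction), `neutral` (never read by any interaction;
#' the within-genome benchmark for the neutral evolutionary rate) and `sender`
#' (read when the protein acts on a target).
#' @return `c("receiver", "neutral", "sender")`
#' @export
protein_domains <- function() c("receiver", "neutral", "sender")

# Column indices of one domain inside the flat bit layout of a genotype row.
# Layout: proteins in canonical order, domains receiver|neutral|sender within
# each protein, sites 1..L within each domain.
domain_cols <- function(protein, domain, L, proteins = host_proteins()) {
  p <- match(protein, proteins)
  d <- match(domain, protein_domains())
  if (is.na(p)) stop("unknown protein label: ", protein)
  if (is.na(d)) stop("unknown domain label: ", domain)
  ((p - 1L) * 3L + (d - 1L)) * L + seq_len(L)
}
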