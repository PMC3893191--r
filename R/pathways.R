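STANDARD_AA <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val")
OBLIGATE_ESSENTIAL <- c("Thr", "Val", "Met", "Leu", "Ile", "Phe", "Lys", "Trp")

#' Load amino-acid biosynthesis pathway models
#'
#' Reads the pathway-model table: one row per (amino acid, route, step, KO
#' id), KOs within a step interchangeable, with an essentiality flag
#' (`yes` for the eight obligate vertebrate-essential amino acids, `conditional`
#' for Arg/His, `no` otherwise). The packaged fixture covers all 20 standard
#' amino acids with condensed single-route step lists following standard
#' KEGG module structure.
#'
#' @param path TSV path; `NULL` loads the packaged fixture.
#' @return named list of models; each has `amino_acid`, `essential`,
#'   `conditional`, `routes` (list of routes, each a list of steps, each a
#'   character vector of interchangeable KO ids) and `n_steps` (steps of
#'   the shortest route).
#' @export
load_pathway_models <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "aa_pathways.tsv", package = "holotome")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty pathway model file")
  need <- c("amino_acid", "route", "step", "ko", "essential")
  if (!all(need %in% names(tab)))
    stop("pathway file must have columns: ", paste(need, collapse = ", "))
  bad_aa <- setdiff(unique(tab$amino_acid), STANDARD_AA)
  if (length(bad_aa))
    stop("amino acid outside the standard 20: ", paste(bad_aa, collapse = ", "))
  key <- paste(tab$amino_acid, tab$route, tab$step, tab$ko)
  if (anyDuplicated(key))
    stop("duplicate (amino acid, route, step, KO) rows: ",
         key[duplicated(key)][1])
  models <- lapply(split(tab, tab$amino_acid), function(t) {
    routes <- lapply(split(t, t$route), function(r) {
      lapply(split(r, r$step), function(s) sort(unique(s$ko)))
    })
    ess <- unique(t$essential)
    if (length(ess) != 1)
      stop("inconsistent essential flag for ", t$amino_acid[1])
    list(amino_acid = t$amino_acid[1],
         essential = ess == "yes",
         conditional = ess == "conditional",
         routes = unname(routes),
         n_steps = min(vapply(routes, length, integer(1))))
  })
  models[order(names(models))]
}

#' @rdname load_pathway_models
#' @param models model list to serialise.
#' @param path output TSV path.
#' @export
write_pathway_models <- function(models, path) {
  rows <- do.call(rbind, lapply(models, function(m) {
    do.call(rbind, lapply(seq_along(m$routes), function(ri) {
      do.call(rbind, lapply(seq_along(m$routes[[ri]]), function(si) {
        data.frame(amino_acid = m$amino_acid, route = ri, step = si,
                   ko = m$routes[[ri]][[si]],
                   essential = if (m$essential) "yes"
                   else if (m$conditional) "conditional" else "no",
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Producibility of one amino acid from a KO set
#'
#' A pathway step is present when the KO set intersects its interchangeable
#' enzyme set. Routes are scored by their number of missing steps and the
#' best (fewest-missing) route is taken. Status is `PRODUCIBLE` with no
#' missing step, `PRODUCIBLE_WITH_GAPS` with 1..`tolerance` missing
#' (pathways missing one or two enzymes are taken into consideration by
#' default), `NOT_PRODUCIBLE` otherwise. Monotone: adding KOs never
#' increases the missing-step count.
#'
#' @param ko_presence character vector of KO ids present in an organism.
#' @param model one model from [load_pathway_models()].
#' @param tolerance missing steps still counted as producible (>= 0).
#' @return list with `amino_acid`, `n_missing_steps`, `status`.
#' @export
producibility <- function(ko_presence, model, tolerance = 2) {
  stopifnot(tolerance >= 0)
  if (is.null(model$routes) || length(model$routes) == 0)
    stop("empty pathway model")
  missing_per_route <- vapply(model$routes, function(steps)
    sum(!vapply(steps, function(kos) any(kos %in% ko_presence), logical(1))),
    integer(1))
  n_missing <- min(missing_per_route)
  status <- if (n_missing == 0) "PRODUCIBLE"
  else if (n_missing <= tolerance) "PRODUCIBLE_WITH_GAPS"
  else "NOT_PRODUCIBLE"
  list(amino_acid = model$amino_acid, n_missing_steps = n_missing,
       status = status)
}

#' Host-symbiont complementarity in amino-acid biosynthesis
#'
#' Classifies each amino acid by which organism(s) can produce it
#' (producible includes "with gaps" under the tolerance): `BOTH`,
#' `HOST_ONLY`, `SYMBIONT_ONLY`, `SPLIT` (neither organism alone, but the
#' union of their KO sets is producible — enzymes split across the
#' partners), or `NEITHER`. The classes partition the amino-acid set.
#'
#' @param host_kos,symbiont_kos KO id vectors for the two organisms.
#' @param models model list covering the 20 standard amino acids.
#' @param tolerance passed to [producibility()].
#' @return list with `table` (per amino acid: statuses, missing counts,
#'   class, essential flags) and `summary` (class counts overall and for
#'   the obligate-essential subset).
#' @export
complementarity <- function(host_kos, symbiont_kos, models, tolerance = 2) {
  missing_models <- setdiff(STANDARD_AA, names(models))
  if (length(missing_models))
    stop("missing pathway model for: ", paste(missing_models, collapse = ", "))
  union_kos <- union(host_kos, symbiont_kos)
  rows <- lapply(models[STANDARD_AA], function(m) {
    ph <- producibility(host_kos, m, tolerance)
    ps <- producibility(symbiont_kos, m, tolerance)
    pu <- producibility(union_kos, m, tolerance)
    ok_h <- ph$status != "NOT_PRODUCIBLE"
    ok_s <- ps$status != "NOT_PRODUCIBLE"
    cls <- if (ok_h && ok_s) "BOTH"
    else if (ok_h) "HOST_ONLY"
    else if (ok_s) "SYMBIONT_ONLY"
    else if (pu$status != "NOT_PRODUCIBLE") "SPLIT"
    else "NEITHER"
    data.frame(amino_acid = m$amino_acid, essential = m$essential,
               conditional = m$conditional,
               host_status = ph$status, host_missing = ph$n_missing_steps,
               symbiont_status = ps$status,
               symbiont_missing = ps$n_missing_steps,
               class = cls, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  classes <- c("BOTH", "HOST_ONLY", "SYMBIONT_ONLY", "SPLIT", "NEITHER")
  count <- function(t) vapply(classes, function(cl) sum(t$class == cl),
                              integer(1))
  list(table = tab,
       summary = list(overall = count(tab),
                      essential = count(tab[tab$essential, , drop = FALSE])))
}

#' Default pathway gap plan for the synthetic holobiont
#'
#' The designed enzyme deletions that give the synthetic dataset its
#' ground-truth complementarity structure: four lysine-pathway enzymes
#' removed from both organisms (lysine producible by neither), the cysteine
#' route broken in the symbiont only (cysteine host-only), the methionine
#' route split between host (upstream aspartate-family steps) and symbiont
#' (downstream steps) so only the union is complete, and the
#' branched-chain/aromatic essential pathways removed from the host
#' (symbiont-only). Deletions act on the organism-wide KO set, so the
#' upstream aspartate-family deletions in the symbiont also make threonine
#' host-only.
#'
#' @return nested list: amino acid -> organism (`HOST`/`SYMBIONT`) -> KO ids
#'   to delete.
#' @export
default_gap_plan <- function() {
  list(
    Lys = list(HOST = c("K01714", "K00215", "K01778", "K01586"),
               SYMBIONT = c("K01714", "K00215", "K01778", "K01586")),
    Met = list(HOST = c("K00651", "K01739", "K01760", "K00548", "K00549"),
               SYMBIONT = c("K00928", "K00133", "K00003")),
    Cys = list(SYMBIONT = c("K01251", "K01697", "K01758")),
    Val = list(HOST = c("K01652", "K01653", "K00053", "K01687", "K00826")),
    Ile = list(HOST = c("K01754")),
    Leu = list(HOST = c("K01649", "K01703", "K01704", "K00052")),
    Phe = list(HOST = c("K01626", "K01735", "K03785", "K00014", "K00891",
                        "K00800", "K01736", "K01850", "K04518")),
    Trp = list(HOST = c("K01657", "K00766", "K01609", "K01695", "K01696"))
  )
}

#' Build per-organism KO tables from pathway models and a gap plan
#'
#' The host table carries every KO of every pathway minus the host
#' deletions; likewise for the symbiont. Each retained KO is attached to a
#' contig id (supplied bin members, recycled at random, or synthetic
#' placeholder ids).
#'
#' @param models pathway models ([load_pathway_models()]).
#' @param gap_plan nested list amino acid -> organism -> KO ids to delete;
#'   every KO must exist in the models.
#' @param host_contig_ids,symbiont_contig_ids optional contig ids to attach
#'   KOs to.
#' @return list with `host` and `symbiont` two-column tables
#'   (`contig_id`, `ko`) and `deleted` (per-organism deleted KO sets).
#' @export
make_ko_tables <- function(models, gap_plan = default_gap_plan(),
                           host_contig_ids = NULL,
                           symbiont_contig_ids = NULL) {
  all_kos <- sort(unique(unlist(lapply(models, function(m)
    unlist(m$routes)))))
  plan_kos <- unique(unlist(gap_plan))
  unknown <- setdiff(plan_kos, all_kos)
  if (length(unknown))
    stop("gap plan names KO ids absent from the pathway models: ",
         paste(unknown, collapse = ", "))
  del <- function(org) unique(unlist(lapply(gap_plan, function(g) g[[org]])))
  del_host <- del("HOST")
  del_sym <- del("SYMBIONT")
  mk <- function(kos, ids, prefix) {
    if (is.null(ids)) ids <- sprintf("%s_%04d", prefix, seq_along(kos))
    else ids <- sample(ids, length(kos), replace = TRUE)
    data.frame(contig_id = ids, ko = kos, stringsAsFactors = FALSE)
  }
  list(host = mk(setdiff(all_kos, del_host), host_contig_ids, "hostko"),
       symbiont = mk(setdiff(all_kos, del_sym), symbiont_contig_ids, "symko"),
       deleted = list(HOST = del_host, SYMBIONT = del_sym))
}
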