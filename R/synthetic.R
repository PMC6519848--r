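#' The TOY-8 worked fixture
#'
#' An eight-vertex miniature of the integrated network exercising the
#' enzyme and metabolic-transcription-factor motifs: genes g1/g2 encode
#' monomers p1/p2; p1 catalyses reaction r1 converting compound c1 to c2;
#' c2 binds p2 into the metabolic regulator complex pc1, which activates
#' g1 and inhibits g2. Its functional three-domain fixed point is
#' RD = {g1, g2}, PI = {p1, p2, pc1}, MD = {r1, c1, c2}.
#'
#' @return An `annotated_graph` with 8 vertices and 9 edges.
#' @export
toy8_graph <- function() {
  v <- data.frame(
    id = c("g1", "g2", "p1", "p2", "pc1", "r1", "c1", "c2"),
    vtype = c("gene", "gene", "protein-monomer", "protein-monomer",
              "protein-compound-complex", "reaction", "compound", "compound"),
    compartment = c(NA, NA, "c", "c", "c", NA, "c", "c"),
    name = c("gene-1", "gene-2", "enzyme-1", "regulator-apo", "regulator-holo",
             "1.1.1.1", "substrate", "effector"),
    stringsAsFactors = FALSE)
  e <- data.frame(
    source = c("g1", "g2", "p1", "c1", "r1", "c2", "p2", "pc1", "pc1"),
    target = c("p1", "p2", "r1", "r1", "c2", "pc1", "pc1", "g1", "g2"),
    etype = c("translation-encoding", "translation-encoding", "catalysis",
              "educt", "product", "complex-formation", "complex-formation",
              "regulation", "regulation"),
    stoichiometry = c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L),
    regulation_mode = c(NA, NA, NA, NA, NA, NA, NA, 1L, -1L),
    logic = c("disjunct", "disjunct", "disjunct", "conjunct", "disjunct",
              "conjunct", "conjunct", NA, NA),
    reg_id = c(NA, NA, NA, NA, NA, NA, NA, "REG-1", "REG-2"),
    stringsAsFactors = FALSE)
  annotated_graph(v, e)
}

#' Parameters for the synthetic network generator
#'
#' Defaults describe a ~200-vertex network with the qualitative features
#' of the integrated *E. coli* reconstruction at miniature scale:
#' a metabolic core of compounds and (partly reversible, enzyme-catalysed)
#' reactions, genes split between enzyme-encoding and regulator-encoding
#' roles, metabolic transcription factors active only as protein-compound
#' complexes, and a heavy-tailed regulator out-degree mimicking global
#' regulators.
#'
#' @param n_genes Number of genes (each encodes one protein monomer).
#' @param n_compounds Number of small compounds.
#' @param n_reactions Number of reaction records (reversible ones split
#'   into two vertices).
#' @param frac_tf_genes Fraction of genes encoding transcription factors.
#' @param frac_metabolic_genes Fraction of genes encoding enzymes.
#' @param frac_metabolic_tfs Fraction of transcription factors active only
#'   as a protein-compound (metabolite-bound) complex.
#' @param regulation_density Probability that a gene is transcriptionally
#'   regulated.
#' @param reversible_fraction Fraction of reversible reactions.
#' @param frac_complex_enzymes Fraction of enzyme-catalysed reactions
#'   catalysed by a protein-protein complex rather than a monomer.
#' @param n_rna_complexes Number of regulatory protein-RNA complexes.
#' @param reaction_regulation Expected number of direct (allosteric-like)
#'   compound-to-reaction regulation edges.
#' @param direct_regulation Number of direct cross-domain regulatory links
#'   in each direction: transcription factors regulating reaction activity
#'   (regulatory to metabolic) and metabolites regulating genes
#'   (metabolic to regulatory).
#' @param tail_exponent Pareto tail exponent of regulator out-degree
#'   propensities (smaller = heavier tail, more global regulators).
#' @param seed Integer seed; identical parameters and seed give an
#'   identical graph.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_genes = 56, n_compounds = 40, n_reactions = 28,
                             frac_tf_genes = 0.12, frac_metabolic_genes = 0.66,
                             frac_metabolic_tfs = 0.5, regulation_density = 0.4,
                             reversible_fraction = 0.2, frac_complex_enzymes = 0.2,
                             n_rna_complexes = 1, reaction_regulation = 2,
                             direct_regulation = 2, tail_exponent = 2, seed = 1L) {
  p <- list(n_genes = n_genes, n_compounds = n_compounds, n_reactions = n_reactions,
            frac_tf_genes = frac_tf_genes, frac_metabolic_genes = frac_metabolic_genes,
            frac_metabolic_tfs = frac_metabolic_tfs,
            regulation_density = regulation_density,
            reversible_fraction = reversible_fraction,
            frac_complex_enzymes = frac_complex_enzymes,
            n_rna_complexes = n_rna_complexes,
            reaction_regulation = reaction_regulation,
            direct_regulation = direct_regulation,
            tail_exponent = tail_exponent, seed = as.integer(seed))
  counts <- unlist(p[c("n_genes", "n_compounds", "n_reactions", "n_rna_complexes")])
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  fr <- unlist(p[c("frac_tf_genes", "frac_metabolic_genes", "frac_metabolic_tfs",
                   "regulation_density", "reversible_fraction", "frac_complex_enzymes")])
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (p$frac_tf_genes + p$frac_metabolic_genes > 1)
    stop("frac_tf_genes + frac_metabolic_genes must not exceed 1", call. = FALSE)
  if (p$n_rna_complexes > 0 && p$n_genes < 2 * p$n_rna_complexes + 1)
    stop("protein-RNA complexes requested with too few genes", call. = FALSE)
  if (p$n_reactions > 0 && p$n_compounds < 2)
    stop("reactions requested with fewer than two compounds", call. = FALSE)
  structure(p, class = "generator_params")
}

#' Named parameter presets
#' @param preset `"toy"` (the TOY-8 fixture), `"small"` or `"ecoli-like"`
#'   (a few hundred vertices with pronounced interface structure).
#' @param seed Seed passed through to [generator_params()].
#' @return A `generator_params` (or `NULL` for `"toy"`, which is fixed).
#' @export
preset_params <- function(preset = c("small", "ecoli-like", "toy"), seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
         toy = NULL,
         small = generator_params(n_genes = 14, n_compounds = 10, n_reactions = 8,
                                  n_rna_complexes = 0, reaction_regulation = 0,
                                  seed = seed),
         `ecoli-like` = generator_params(n_genes = 220, n_compounds = 150,
                                         n_reactions = 120, frac_tf_genes = 0.12,
                                         frac_metabolic_genes = 0.65,
                                         frac_metabolic_tfs = 0.4,
                                         regulation_density = 0.45,
                                         reversible_fraction = 0.25,
                                         frac_complex_enzymes = 0.25,
                                         n_rna_complexes = 2,
                                         reaction_regulation = 6,
                                         direct_regulation = 8, seed = seed))
}

#' Generate a synthetic annotated network with planted domain labels
#'
#' Builds a type-grammar-respecting network (educt/product edges touch
#' reactions, encoding edges run gene to protein, regulation sources are
#' proteins, complexes or genes never reactions) and records the
#' construction-role ground truth for every vertex: regulated genes and
#' regulator-encoding genes are regulatory (RD); enzymes of regulated
#' genes, enzyme complexes containing them, metabolic transcription-factor
#' complexes and their protein members are interface (PI); compounds,
#' reactions, unregulated enzymes and otherwise uninvolved proteins are
#' metabolic (MD); pure transcription factors and protein-RNA regulators
#' are RD. Weak connectivity is enforced by minimal grammar-respecting
#' bridging edges.
#'
#' @param params A `generator_params`.
#' @return List with `$graph` (an `annotated_graph`), `$truth` (a planted
#'   three-domain `domain_partition`) and `$flagged` (ids of vertices with
#'   mixed construction wiring, excluded from recovery claims).
#' @export
generate_network <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  set.seed(params$seed)
  p <- params
  fmt <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

  genes <- fmt("G", p$n_genes)
  monomers <- sub("^G", "P", genes)
  compounds <- fmt("C", p$n_compounds)

  # gene roles
  n_tf <- round(p$frac_tf_genes * p$n_genes)
  n_enz <- min(round(p$frac_metabolic_genes * p$n_genes), p$n_genes - n_tf)
  roles <- sample(c(rep("tf", n_tf), rep("enzyme", n_enz),
                    rep("other", p$n_genes - n_tf - n_enz)))
  names(roles) <- genes

  v <- list(); e <- list()
  add_v <- function(id, vtype, compartment = NA_character_, name = NA_character_)
    v[[length(v) + 1L]] <<- data.frame(id = id, vtype = vtype,
                                       compartment = compartment, name = name)
  add_e <- function(source, target, etype, stoichiometry = 0L,
                    regulation_mode = NA_integer_, logic = NA_character_,
                    reg_id = NA_character_)
    e[[length(e) + 1L]] <<- data.frame(source = source, target = target,
                                       etype = etype,
                                       stoichiometry = as.integer(stoichiometry),
                                       regulation_mode = regulation_mode,
                                       logic = logic, reg_id = reg_id)

  for (g in genes) add_v(g, "gene")
  for (m in monomers) add_v(m, "protein-monomer", "c")
  for (cc in compounds) add_v(cc, "compound", "c")
  for (i in seq_len(p$n_genes))
    add_e(genes[i], monomers[i], "translation-encoding", logic = "disjunct")

  # reactions over the compound pool; a fraction reversible (split twins)
  n_rev <- round(p$reversible_fraction * p$n_reactions)
  rev_flag <- rep(c(TRUE, FALSE), c(n_rev, p$n_reactions - n_rev))
  reactions <- fmt("R", p$n_reactions)
  rxn_vertices <- character(0)
  for (i in seq_len(p$n_reactions)) {
    r <- reactions[i]
    ne <- sample(1:min(3, p$n_compounds - 1), 1)
    educts <- sample(compounds, ne)
    products <- sample(setdiff(compounds, educts), sample(1:min(3, p$n_compounds - ne), 1))
    coeff <- stats::setNames(sample(1:2, length(c(educts, products)), replace = TRUE),
                             c(educts, products))
    twins <- if (rev_flag[i]) c(r, paste0(r, "_REV")) else r
    for (k in seq_along(twins)) {
      add_v(twins[k], "reaction")
      el <- if (k == 1L) educts else products
      pr <- if (k == 1L) products else educts
      for (x in el) add_e(x, twins[k], "educt", coeff[[x]], logic = "conjunct")
      for (x in pr) add_e(twins[k], x, "product", coeff[[x]], logic = "disjunct")
    }
    rxn_vertices <- c(rxn_vertices, twins)
  }

  # enzymes: monomers (or complexes of them) catalyse the reactions
  enz_monomers <- monomers[roles == "enzyme"]
  enz_complexes <- character(0)
  complex_members <- list()
  catalyzed <- reactions[stats::runif(p$n_reactions) < 0.9]
  n_cx_rxn <- round(p$frac_complex_enzymes * length(catalyzed))
  cx_rxn <- if (n_cx_rxn > 0 && length(enz_monomers) >= 2)
    sample(catalyzed, n_cx_rxn) else character(0)
  pool <- sample(enz_monomers)   # disjoint memberships: subunit sharing
  for (i in seq_along(cx_rxn)) { # would couple the complexes' domain roles
    if (length(pool) < 2) { cx_rxn <- cx_rxn[seq_len(i - 1L)]; break }
    cx <- sprintf("ECPLX%03d", i)
    members <- pool[seq_len(sample(2:min(3, length(pool)), 1))]
    pool <- setdiff(pool, members)
    add_v(cx, "protein-protein-complex", "c")
    for (m in members) add_e(m, cx, "complex-formation", 1L, logic = "conjunct")
    enz_complexes <- c(enz_complexes, cx)
    complex_members[[cx]] <- members
  }
  # complex subunits do not moonlight as independent catalysts: a subunit
  # catalysing on its own would make its complex's domain role ambiguous
  free_monomers <- setdiff(enz_monomers,
                           unlist(complex_members, use.names = FALSE))
  catalyst_of <- setNames(vector("list", length(reactions)), reactions)
  for (i in seq_along(reactions)) {
    r <- reactions[i]
    if (!r %in% catalyzed || !(length(free_monomers) || length(enz_complexes))) next
    enz <- if (r %in% cx_rxn) enz_complexes[match(r, cx_rxn)]
           else if (length(free_monomers)) sample(free_monomers, 1) else next
    twins <- if (rev_flag[i]) c(r, paste0(r, "_REV")) else r
    for (t in twins) add_e(enz, t, "catalysis", logic = "disjunct")
    catalyst_of[[r]] <- enz
  }

  # transcription factors: a fraction act only as metabolite-bound complexes
  tf_monomers <- monomers[roles == "tf"]
  n_mtf <- round(p$frac_metabolic_tfs * length(tf_monomers))
  mtf <- if (n_mtf > 0) sample(tf_monomers, n_mtf) else character(0)
  regulators <- setdiff(tf_monomers, mtf)
  mtf_complexes <- character(0)
  for (i in seq_along(mtf)) {
    cx <- sprintf("TFCPLX%03d", i)
    ligand <- sample(compounds, 1)
    add_v(cx, "protein-compound-complex", "c")
    add_e(mtf[i], cx, "complex-formation", 1L, logic = "conjunct")
    add_e(ligand, cx, "complex-formation", 1L, logic = "conjunct")
    mtf_complexes <- c(mtf_complexes, cx)
    complex_members[[cx]] <- mtf[i]
  }
  regulators <- c(regulators, mtf_complexes)

  # regulatory protein-RNA complexes (RNA collapsed to its encoding gene)
  other_genes <- genes[roles == "other"]
  rna_complexes <- character(0)
  if (p$n_rna_complexes > 0 && length(other_genes) >= 2 * p$n_rna_complexes) {
    picked <- sample(other_genes, 2 * p$n_rna_complexes)
    for (i in seq_len(p$n_rna_complexes)) {
      cx <- sprintf("RNACPLX%03d", i)
      rna_gene <- picked[2 * i - 1L]
      prot_gene <- picked[2 * i]
      add_v(cx, "protein-RNA-complex", "c")
      add_e(rna_gene, cx, "transcription-encoding", 1L, logic = "conjunct")
      add_e(sub("^G", "P", prot_gene), cx, "complex-formation", 1L, logic = "conjunct")
      rna_complexes <- c(rna_complexes, cx)
      complex_members[[cx]] <- sub("^G", "P", prot_gene)
    }
    regulators <- c(regulators, rna_complexes)
  }

  # transcriptional regulation with heavy-tailed regulator propensity;
  # every regulator gets at least one target where the pool allows, so the
  # construction role of each regulator is realised in the wiring
  flagged <- character(0)
  regulated <- genes[stats::runif(p$n_genes) < p$regulation_density]
  if (length(regulated) && length(regulators)) {
    w <- stats::runif(length(regulators))^(-1 / p$tail_exponent)
    reg_of <- sample(regulators, length(regulated), replace = TRUE, prob = w)
    k <- min(length(regulators), length(regulated))
    reg_of[sample.int(length(regulated), k)] <- sample(regulators)[seq_len(k)]
    modes <- sample(c(1L, -1L, 0L), length(regulated), replace = TRUE,
                    prob = c(0.55, 0.4, 0.05))
    for (i in seq_along(regulated))
      add_e(reg_of[i], regulated[i], "regulation", regulation_mode = modes[i],
            reg_id = sprintf("REG%04d", i))
    reg_sources <- unique(reg_of)
  } else {
    regulated <- character(0)
    reg_sources <- character(0)
  }

  # direct cross-domain links: regulatory-side regulators acting on
  # reaction activity, and metabolites directly regulating genes
  n_dr <- p$direct_regulation
  rd_regulators <- setdiff(regulators, mtf_complexes)
  if (n_dr > 0 && length(rd_regulators) && p$n_reactions > 0) {
    src <- sample(rd_regulators, n_dr, replace = TRUE)
    tgt <- sample(reactions, n_dr, replace = TRUE)
    for (i in seq_len(n_dr)) {
      twins <- if (rev_flag[match(tgt[i], reactions)])
        c(tgt[i], paste0(tgt[i], "_REV")) else tgt[i]
      for (t in twins)
        add_e(src[i], t, "regulation", regulation_mode = -1L,
              reg_id = sprintf("DREG%04d", i))
    }
    reg_sources <- unique(c(reg_sources, src))
  }
  if (n_dr > 0 && p$n_genes > 0) {
    src <- sample(compounds, min(n_dr, p$n_compounds))
    tgt <- sample(genes, length(src))
    for (i in seq_along(src))
      add_e(src[i], tgt[i], "regulation", regulation_mode = 1L,
            reg_id = sprintf("UREG%04d", i))
    regulated <- unique(c(regulated, tgt))
  }

  idle <- setdiff(regulators, reg_sources)
  # regulators without realised targets have ambiguous construction intent
  for (cx in idle) {
    flagged <- c(flagged, cx, complex_members[[cx]],
                 sub("^P", "G", intersect(c(cx, complex_members[[cx]]), monomers)))
  }

  # sparse direct compound-on-reaction (allosteric-like) regulation;
  # a regulated reversible reaction is regulated in both directions
  n_rr <- min(p$reaction_regulation, p$n_reactions)
  if (n_rr > 0) {
    rr_base <- sample(reactions, n_rr)
    rr_s <- sample(compounds, n_rr, replace = TRUE)
    for (i in seq_len(n_rr)) {
      twins <- if (rev_flag[match(rr_base[i], reactions)])
        c(rr_base[i], paste0(rr_base[i], "_REV")) else rr_base[i]
      for (t in twins)
        add_e(rr_s[i], t, "regulation", regulation_mode = -1L,
              reg_id = sprintf("RREG%04d", i))
    }
  }

  vdf <- do.call(rbind, v)
  edf <- do.call(rbind, e)
  key <- paste(edf$source, edf$target, edf$etype, sep = "\r")
  edf <- edf[!duplicated(key), , drop = FALSE]
  g <- annotated_graph(vdf, edf)

  # enforce weak connectivity with minimal grammar-respecting bridges
  bridged <- .bridge_components(g)
  flagged <- unique(c(flagged, bridged$flagged))

  truth <- .planted_labels(bridged, roles, regulated, complex_members,
                           mtf_complexes, rna_complexes, catalyst_of)
  list(graph = bridged$graph, truth = truth, flagged = flagged)
}

.bridge_components <- function(g) {
  flagged <- character(0)
  repeat {
    mem <- .component_membership(g, "weak")
    if (length(unique(mem)) <= 1L) break
    main_ids <- .largest_component_ids(mem)
    other <- names(mem)[!names(mem) %in% main_ids]
    cc <- mem[other[1L]]
    comp_ids <- names(mem)[mem == cc]
    vt <- setNames(g$vertices$vtype, g$vertices$id)
    main_rxn <- main_ids[vt[main_ids] == "reaction"]
    # direction twins always share their base's component, so anchoring on
    # base reactions loses no bridging options
    main_rxn <- main_rxn[!endsWith(main_rxn, "_REV")]
    # a reversible target needs the mirrored edge on its direction twin
    rxn_twins <- function(r) {
      tw <- paste0(r, "_REV")
      if (tw %in% names(vt)) c(r, tw) else r
    }
    # prefer attaching a compound as an extra educt of a main reaction
    cand <- comp_ids[vt[comp_ids] == "compound"]
    if (length(cand) && length(main_rxn)) {
      tw <- rxn_twins(main_rxn[1L])
      new_e <- data.frame(source = c(cand[1L], if (length(tw) > 1) tw[2L]),
                          target = c(tw[1L], if (length(tw) > 1) cand[1L]),
                          etype = c("educt", if (length(tw) > 1) "product"),
                          stoichiometry = 1L,
                          logic = c("conjunct", if (length(tw) > 1) "disjunct"))
    } else {
      prot <- comp_ids[.is_protein(vt[comp_ids])]
      if (length(prot) && length(main_rxn)) {
        tw <- rxn_twins(main_rxn[1L])
        new_e <- data.frame(source = prot[1L], target = tw,
                            etype = "catalysis", stoichiometry = 0L,
                            logic = "disjunct")
        flagged <- c(flagged, prot[1L])
      } else {
        main_cmp <- main_ids[vt[main_ids] == "compound"]
        rxn <- comp_ids[vt[comp_ids] == "reaction"]
        if (length(rxn) && length(main_cmp)) {
          new_e <- data.frame(source = rxn[1L], target = main_cmp[1L],
                              etype = "product", stoichiometry = 1L,
                              logic = "disjunct")
        } else stop("cannot bridge components under the type grammar", call. = FALSE)
      }
    }
    g$edges <- .coerce_frame(rbind(.coerce_frame(new_e, .e_cols),
                                   g$edges), .e_cols)
  }
  list(graph = g, flagged = flagged)
}

# Construction-role ground truth; see generate_network() docs.
.planted_labels <- function(bridged, roles, regulated, complex_members,
                            mtf_complexes, rna_complexes, catalyst_of) {
  g <- bridged$graph
  vt <- setNames(g$vertices$vtype, g$vertices$id)
  e <- g$edges
  lab <- setNames(rep("MD", length(vt)), names(vt))

  base_gene <- function(m) sub("^P", "G", m)
  catalysts <- unique(e$source[e$etype == "catalysis"])

  # genes
  for (gn in names(roles)) {
    reg_encoding <- roles[[gn]] == "tf" ||
      gn %in% unlist(lapply(rna_complexes, function(cx)
        c(e$source[e$target == cx & e$etype == "transcription-encoding"],
          base_gene(complex_members[[cx]]))), use.names = FALSE)
    if (gn %in% regulated || reg_encoding) lab[gn] <- "RD"
  }

  # interface membership of enzyme machinery: catalysts whose (member)
  # genes include a regulated one, and all members of such complexes
  for (cat in catalysts) {
    if (!cat %in% names(vt)) next
    members <- if (vt[[cat]] == "protein-monomer") cat else complex_members[[cat]]
    if (is.null(members)) members <- character(0)
    if (any(base_gene(members) %in% regulated)) {
      lab[cat] <- "PI"
      lab[members] <- "PI"
    }
  }
  # metabolic TF complexes and their protein members are interface
  for (cx in mtf_complexes) {
    lab[cx] <- "PI"
    lab[complex_members[[cx]]] <- "PI"
  }
  # pure transcription factors and protein-RNA regulators are regulatory
  pure_tf <- names(vt)[vt == "protein-monomer" &
                         names(vt) %in% setdiff(unique(e$source[e$etype == "regulation"]),
                                                c(mtf_complexes, rna_complexes))]
  lab[pure_tf] <- "RD"
  for (cx in rna_complexes) {
    lab[cx] <- "RD"
    lab[complex_members[[cx]]] <- "RD"
  }
  # remaining proteins of regulated genes stay regulatory-side products
  others <- names(vt)[vt == "protein-monomer" & lab[names(vt)] == "MD"]
  for (m in others)
    if (base_gene(m) %in% regulated && !m %in% catalysts) lab[m] <- "RD"

  domain_partition(lab, "functional", 3)
}

#' Write an annotated graph as miniature BioCyc-dialect flat files
#'
#' Emits the eight-file fixture directory such that
#' [reconstruct_network()] on it yields a graph isomorphic to the largest
#' weakly connected component of `g` (identical ids and attributes).
#' Reversible reactions are recognised by their `_REV` twin and written as
#' one `REVERSIBLE` record; RNA components of protein-RNA complexes are
#' written through synthesised `<gene>-RNA` accessions in `rnas.dat`;
#' regulation edges sharing a `reg_id` merge into one record with a
#' multi-valued `REGULATED-ENTITY` (and edges onto `_REV` twins are
#' implied by their base reaction, hence omitted).
#'
#' @param g An `annotated_graph` respecting the type grammar.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
emit_flat_files <- function(g, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- g$vertices; e <- g$edges
  vt <- setNames(v$vtype, v$id)
  nm <- setNames(v$name, v$id)
  comp <- setNames(v$compartment, v$id)
  att <- function(key, val) if (!is.na(val) && nzchar(val)) sprintf("%s - %s", key, val)
  rev_base <- v$id[vt == "reaction" & paste0(v$id, "_REV") %in% v$id]

  lines <- list(compounds = character(), genes = character(), rnas = character(),
                proteins = character(), reactions = character(),
                regulation = character(), classes = character())
  pcx <- c("UNIQUE-ID\tCOMPONENTS")

  for (id in v$id[vt == "compound"]) {
    lines$compounds <- c(lines$compounds, sprintf("UNIQUE-ID - %s", id),
                         att("COMMON-NAME", nm[[id]]), att("COMPARTMENT", comp[[id]]),
                         "//")
  }
  # genes; RNA-encoding genes get a synthesised RNA accession
  rna_enc <- e[e$etype == "transcription-encoding", , drop = FALSE]
  for (id in v$id[vt == "gene"]) {
    prod <- e$target[e$source == id & e$etype == "translation-encoding"]
    rna_t <- rna_enc$target[rna_enc$source == id]
    prod_attr <- if (length(prod)) sprintf("PRODUCT - %s", prod[1L])
                 else if (length(rna_t)) sprintf("PRODUCT - %s-RNA", id)
    lines$genes <- c(lines$genes, sprintf("UNIQUE-ID - %s", id),
                     att("COMMON-NAME", nm[[id]]), prod_attr, "//")
    if (length(rna_t))
      lines$rnas <- c(lines$rnas, sprintf("UNIQUE-ID - %s-RNA", id),
                      sprintf("GENE - %s", id), "//")
  }
  # proteins + composition table
  for (id in v$id[.is_protein(vt)]) {
    gene <- e$source[e$target == id & e$etype == "translation-encoding"]
    lines$proteins <- c(lines$proteins, sprintf("UNIQUE-ID - %s", id),
                        att("COMMON-NAME", nm[[id]]), att("COMPARTMENT", comp[[id]]),
                        if (length(gene)) sprintf("GENE - %s", gene[1L]), "//")
    if (vt[[id]] != "protein-monomer") {
      cf <- e[e$target == id & e$etype == "complex-formation", , drop = FALSE]
      entries <- sprintf("%s:%d", cf$source, pmax(cf$stoichiometry, 1L))
      rna_g <- rna_enc$source[rna_enc$target == id]
      if (length(rna_g)) entries <- c(entries, sprintf("%s-RNA:1", rna_g))
      pcx <- c(pcx, sprintf("%s\t%s", id, paste(entries, collapse = " // ")))
    }
  }
  # reactions (skip _REV twins; they are implied by REVERSIBLE)
  for (id in v$id[vt == "reaction" & !endsWith(v$id, "_REV")]) {
    ed <- e[e$target == id & e$etype == "educt", , drop = FALSE]
    pr <- e[e$source == id & e$etype == "product", , drop = FALSE]
    enz <- e$source[e$target == id & e$etype == "catalysis"]
    body <- c(sprintf("UNIQUE-ID - %s", id), att("EC-NUMBER", nm[[id]]))
    for (i in seq_len(nrow(ed)))
      body <- c(body, sprintf("LEFT - %s", ed$source[i]),
                sprintf("^COEFFICIENT - %d", max(ed$stoichiometry[i], 1L)))
    for (i in seq_len(nrow(pr)))
      body <- c(body, sprintf("RIGHT - %s", pr$target[i]),
                sprintf("^COEFFICIENT - %d", max(pr$stoichiometry[i], 1L)))
    body <- c(body,
              sprintf("REACTION-DIRECTION - %s",
                      if (id %in% rev_base) "REVERSIBLE" else "LEFT-TO-RIGHT"),
              vapply(enz, function(x) sprintf("ENZYMES - %s", x), character(1)))
    lines$reactions <- c(lines$reactions, body, "//")
  }
  # regulation grouped by reg_id; edges onto _REV twins are implied
  reg <- e[e$etype == "regulation", , drop = FALSE]
  if (nrow(reg)) {
    reg <- reg[!(endsWith(reg$target, "_REV") & sub("_REV$", "", reg$target) %in% rev_base), ,
               drop = FALSE]
    reg$gid <- ifelse(is.na(reg$reg_id),
                      sprintf("SYNREG%04d", seq_len(nrow(reg))), reg$reg_id)
    for (gid in unique(reg$gid)) {
      rr <- reg[reg$gid == gid, , drop = FALSE]
      mode <- rr$regulation_mode[1L]
      lines$regulation <- c(
        lines$regulation, sprintf("UNIQUE-ID - %s", gid),
        att("COMMON-NAME", rr$reg_name[1L]),
        sprintf("REGULATOR - %s", rr$source[1L]),
        sprintf("REGULATED-ENTITY - %s", rr$target),
        sprintf("MODE - %s", c(`-1` = "-", `0` = "0", `1` = "+")[as.character(mode)]),
        "//")
    }
  }
  header <- "# miniature BioCyc-dialect fixture written by regmetnet"
  for (fn in names(lines))
    writeLines(c(header, lines[[fn]]), file.path(dir, paste0(fn, ".dat")))
  writeLines(pcx, file.path(dir, "protcplxs.col"))
  invisible(dir)
}
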