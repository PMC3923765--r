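# Synthetic-data generators. Every module of the package is testable
# offline: these emit text in exactly the dialects the readers consume.
# All generators are deterministic for a fixed seed.

#' Generate a protein-protein interaction network in SIF format
#'
#' A connected preferential-attachment graph (a spanning tree grown by
#' degree-weighted attachment, densified with degree-weighted extra edges)
#' with exactly `n_edges` unique unordered interaction pairs, relation type
#' "pp" — the structural shape of large PPI data sets.
#'
#' @param n_nodes Number of proteins.
#' @param n_edges Number of interactions; must lie in
#'   `[n_nodes - 1, n_nodes * (n_nodes - 1) / 2]`.
#' @param seed Integer seed.
#' @return SIF text (one tab-separated line per interaction).
#' @export
gen_ppi_sif <- function(n_nodes, n_edges, seed = 1) {
  max_e <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_e || n_edges < n_nodes - 1)
    rlang::abort(sprintf(
      "n_edges must be within [%d, %d] for %d nodes", n_nodes - 1, max_e,
      n_nodes), class = "bnv_param_error")
  set.seed(seed)
  deg <- rep(1L, n_nodes)
  # spanning tree by preferential attachment
  a <- integer(n_edges); b <- integer(n_edges)
  for (i in 2:n_nodes) {
    j <- sample.int(i - 1, 1, prob = deg[seq_len(i - 1)])
    a[i - 1] <- j; b[i - 1] <- i
    deg[j] <- deg[j] + 1L; deg[i] <- deg[i] + 1L
  }
  have <- new.env(hash = TRUE, size = n_edges * 2)
  for (i in seq_len(n_nodes - 1))
    assign(sprintf("%d_%d", a[i], b[i]), TRUE, envir = have)
  need <- n_edges - (n_nodes - 1)
  got <- n_nodes - 1L
  while (need > 0) {
    m <- max(need * 2L, 64L)
    u <- sample.int(n_nodes, m, replace = TRUE, prob = deg)
    v <- sample.int(n_nodes, m, replace = TRUE, prob = deg)
    lo <- pmin(u, v); hi <- pmax(u, v)
    ok <- lo != hi
    lo <- lo[ok]; hi <- hi[ok]
    for (t in seq_along(lo)) {
      key <- sprintf("%d_%d", lo[t], hi[t])
      if (!exists(key, envir = have, inherits = FALSE)) {
        assign(key, TRUE, envir = have)
        got <- got + 1L
        a[got] <- lo[t]; b[got] <- hi[t]
        deg[lo[t]] <- deg[lo[t]] + 1L; deg[hi[t]] <- deg[hi[t]] + 1L
        need <- need - 1L
        if (need == 0L) break
      }
    }
  }
  paste(sprintf("P%05d\tpp\tP%05d", a, b), collapse = "\n")
}

#' Generate a metabolic pathway in KGML
#'
#' A chain-with-branches reaction network: compounds linked by reactions,
#' each catalysed by one enzyme, with every third reaction additionally
#' consuming/producing a shared currency-metabolite pair (ATP/ADP analogs)
#' so that co-factor strategies can be exercised. Every entry carries
#' graphics coordinates on an 80-px grid.
#'
#' @param n_reactions Number of reactions (>= 1).
#' @param seed Integer seed (controls branch placement).
#' @return A list with `kgml` (the XML text) and `cofactor_ids` (entry ids
#'   of the currency metabolites — the side list driving co-factor
#'   handling).
#' @export
gen_metabolic_kgml <- function(n_reactions, seed = 1) {
  if (n_reactions < 1) rlang::abort("n_reactions must be >= 1")
  set.seed(seed)
  grid <- 80
  entries <- character(); reactions <- character()
  next_entry <- 0L
  add_entry <- function(name, type, x, y) {
    next_entry <<- next_entry + 1L
    entries[[length(entries) + 1]] <<- sprintf(
      paste0('    <entry id="%d" name="%s" type="%s"%s>\n',
             '      <graphics name="%s" x="%d" y="%d" width="46" ',
             'height="17" type="rectangle"/>\n    </entry>'),
      next_entry, name, type,
      if (type == "enzyme") sprintf(' reaction="rn:R%05d"',
                                    as.integer(sub(".*E", "", name))) else "",
      sub("^[a-z]+:", "", name), x, y)
    next_entry
  }
  cid <- integer(n_reactions + 1)
  for (j in 0:n_reactions)
    cid[j + 1] <- add_entry(sprintf("cpd:C%05d", j), "compound",
                            grid * (j + 1), 2 * grid)
  atp <- add_entry("cpd:CUR01", "compound", grid, 4 * grid)
  adp <- add_entry("cpd:CUR02", "compound", 2 * grid, 4 * grid)
  branch_at <- if (n_reactions >= 4)
    sort(sample(seq_len(n_reactions), max(1, n_reactions %/% 4)))
    else integer()
  bid <- 0L
  for (i in seq_len(n_reactions)) {
    eid <- add_entry(sprintf("ec:E%05d", i), "enzyme", grid * (i + 1), grid)
    subs <- sprintf('      <substrate id="%d" name="cpd:C%05d"/>',
                    cid[i], i - 1)
    prods <- sprintf('      <product id="%d" name="cpd:C%05d"/>', cid[i + 1], i)
    if (i %% 3 == 0) {
      subs <- c(subs, sprintf('      <substrate id="%d" name="cpd:CUR01"/>',
                              atp))
      prods <- c(prods, sprintf('      <product id="%d" name="cpd:CUR02"/>',
                                adp))
    }
    if (i %in% branch_at) {
      bid <- bid + 1L
      bx <- add_entry(sprintf("cpd:B%05d", bid), "compound",
                      grid * (i + 1), 3 * grid)
      prods <- c(prods, sprintf('      <product id="%d" name="cpd:B%05d"/>',
                                bx, bid))
    }
    reactions[[length(reactions) + 1]] <- paste0(
      sprintf('    <reaction id="%d" name="rn:R%05d" type="irreversible">\n',
              1000L + i, i),
      paste(c(subs, prods), collapse = "\n"), "\n    </reaction>")
  }
  kgml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<pathway name="path:syn00001" org="syn" number="00001" ',
    'title="synthetic pathway">\n',
    paste(unlist(entries), collapse = "\n"), "\n",
    paste(unlist(reactions), collapse = "\n"), "\n</pathway>\n")
  list(kgml = kgml, cofactor_ids = as.character(c(atp, adp)))
}

#' Generate a layered regulatory network model
#'
#' Emulates a signalling cascade: receptors annotated to the plasma
#' membrane, kinases to the cytoplasm, transcription factors to the
#' nucleus, with all edges oriented from the membrane towards the nucleus.
#' 10% of entities receive a second compartment term (ambiguous
#' annotation) and 10% lose their annotation entirely (no information),
#' exercising the red/rose/white ambiguity colouring and the fallback
#' layer.
#'
#' @param n_entities Total entities (>= 4).
#' @param cm A [compartment_model()] (layer vocabulary for the extra
#'   ambiguous terms).
#' @param seed Integer seed.
#' @return A list with `model` (a `bnv_model`) and `roles` (tibble id,
#'   role).
#' @export
gen_regulatory_model <- function(n_entities, cm = compartment_model(),
                                 seed = 1) {
  if (n_entities < 4) rlang::abort("n_entities must be >= 4")
  set.seed(seed)
  n_rec <- max(1, round(n_entities * 0.25))
  n_tf <- max(1, round(n_entities * 0.25))
  n_kin <- n_entities - n_rec - n_tf
  roles <- c(rep("receptor", n_rec), rep("kinase", n_kin), rep("tf", n_tf))
  ids <- sprintf("%s%03d", c("REC", "KIN", "TF")[match(
    roles, c("receptor", "kinase", "tf"))],
    c(seq_len(n_rec), seq_len(n_kin), seq_len(n_tf)))
  base_term <- c(receptor = "plasma membrane", kinase = "cytoplasm",
                 tf = "nucleus")[roles]
  comp <- lapply(base_term, function(t) t)
  # 10% ambiguous (second term), 10% unannotated
  n_amb <- round(n_entities * 0.10)
  n_none <- round(n_entities * 0.10)
  pick <- sample(n_entities, n_amb + n_none)
  amb <- pick[seq_len(n_amb)]
  none <- setdiff(pick, amb)
  for (i in amb) {
    other <- setdiff(c("cytoplasm", "nucleus", "plasma membrane"),
                     base_term[i])
    comp[[i]] <- c(base_term[i], sample(other, 1))
  }
  for (i in none) comp[[i]] <- character()
  model <- network_model()
  model <- add_entities(model, ids,
                        kind = ifelse(roles == "tf", "protein", "protein"),
                        compartments = comp)
  rec <- ids[roles == "receptor"]; kin <- ids[roles == "kinase"]
  tf <- ids[roles == "tf"]
  src <- character(); tgt <- character(); rel <- character()
  for (j in seq_along(kin)) {
    up <- if (j == 1 || stats::runif(1) < 0.5) sample(rec, 1)
      else sample(kin[seq_len(j - 1)], 1)
    src <- c(src, up); tgt <- c(tgt, kin[j])
    rel <- c(rel, sample(c("activation", "phosphorylation"), 1))
  }
  for (t in tf) {
    src <- c(src, sample(kin, 1)); tgt <- c(tgt, t)
    rel <- c(rel, sample(c("activation", "inhibition"), 1))
  }
  model <- add_edges(model, src, tgt, rel)
  list(model = clear_dirty(model),
       roles = tibble::tibble(id = ids, role = roles))
}

#' Generate an omics series with known group structure
#'
#' Log-normal baseline expression per row, multiplicative group effects for
#' a fraction of rows (log2 fold change ramping linearly across the
#' groups — a simple time-course shape), log-normal replicate noise and
#' ~5% missing values. The returned truth table records each row's true
#' effect for recovery tests.
#'
#' @param entity_ids Row identifiers (one feature per entity).
#' @param n_samples Total samples; must be divisible by `n_groups`.
#' @param n_groups Number of sample groups (time points / conditions).
#' @param effect Log2 fold change reached in the last group by affected
#'   rows.
#' @param frac_affected Fraction of rows carrying the effect (default 0.2).
#' @param noise_sd SD of log-normal replicate noise (default 0.15).
#' @param missing_frac Fraction of cells set missing (default 0.05).
#' @param seed Integer seed.
#' @return A list with `series` (a `bnv_series`) and `truth` (tibble id,
#'   effect).
#' @export
gen_omics_series <- function(entity_ids, n_samples, n_groups, effect = 1,
                             frac_affected = 0.2, noise_sd = 0.15,
                             missing_frac = 0.05, seed = 1) {
  if (n_samples %% n_groups != 0)
    rlang::abort("n_samples must be divisible by n_groups")
  set.seed(seed)
  n <- length(entity_ids)
  per <- n_samples / n_groups
  samples <- sprintf("g%d_r%d", rep(seq_len(n_groups), each = per),
                     rep(seq_len(per), n_groups))
  groups <- stats::setNames(
    split(samples, rep(seq_len(n_groups), each = per)),
    sprintf("group%d", seq_len(n_groups)))
  baseline <- stats::rlnorm(n, meanlog = 3, sdlog = 0.8)
  affected <- stats::runif(n) < frac_affected
  eff <- ifelse(affected, effect, 0)
  ramp <- if (n_groups > 1) (seq_len(n_groups) - 1) / (n_groups - 1) else 1
  mu <- outer(baseline, rep(1, n_samples)) *
    2^(outer(eff, ramp[rep(seq_len(n_groups), each = per)]))
  noise <- matrix(stats::rlnorm(n * n_samples, 0, noise_sd), n)
  vals <- mu * noise
  vals[matrix(stats::runif(n * n_samples) < missing_frac, n)] <- NA
  list(series = data_series(vals, as.list(entity_ids), samples = samples,
                            groups = groups, name = "synthetic_omics"),
       truth = tibble::tibble(id = entity_ids, effect = eff))
}
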