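#' Bundled example networks
#'
#' Ready-made atom-transition models:
#' \describe{
#'   \item{`"desk"`}{Compact heterotrophic central-metabolism network used
#'     by the synthetic-experiment machinery: glucose uptake plus an
#'     unlabelled (vacuolar) glucose influx into a hexose-phosphate pool,
#'     aldolase cleavage to triose phosphate, a reversible
#'     triose-phosphate/PEP step, a pyruvate-kinase branch, anaplerotic
#'     PEP + CO2 carboxylation to malate (an EMU convolution node), a
#'     malic-enzyme return, pyruvate decarboxylation and biomass/CO2
#'     outputs. Malate is observed with a fitted unlabelled (vacuolar)
#'     dilution fraction.}
#'   \item{`"chain2"`}{Two-carbon linear chain source -> A -> B -> sink.}
#'   \item{`"condense"`}{Two 1-carbon sources condensing into a 2-carbon
#'     product (convolution).}
#'   \item{`"branch"`}{Two sources (one labelled, one unlabelled) converging
#'     on a single pool.}
#'   \item{`"symmetric"`}{Positionally labelled source feeding a symmetric
#'     (succinate-like) intermediate, for scrambling checks.}
#'   \item{`"arabidopsis"`}{Transcription of the published reaction list of
#'     compartmented central carbon metabolism in heterotrophic arabidopsis
#'     cells (glycolysis in cytosol and plastid, oxidative PPP,
#'     transketolase/transaldolase rearrangements, TCA cycle with succinate
#'     and fumarate scrambling, anaplerosis, starch/sucrose synthesis) with
#'     textbook atom maps. The published model's own maps are not printed,
#'     so positional details of the TCA/PPP maps carry transcription risk;
#'     topology and stoichiometry follow the published table.}
#' }
#'
#' @param name one of the names above.
#' @return an `mfa_model`.
#' @export
mfa_example_model <- function(name = c("desk", "chain2", "condense", "branch",
                                       "symmetric", "arabidopsis")) {
  name <- match.arg(name)
  parse_mfa_model(example_model_text(name))
}

#' @rdname mfa_example_model
#' @export
example_model_text <- function(name = c("desk", "chain2", "condense", "branch",
                                        "symmetric", "arabidopsis")) {
  name <- match.arg(name)
  switch(name,
    desk = c(
      "# compact heterotrophic central-metabolism network",
      "pool GLC.ext 6 source",
      "pool GLC.v 6 source",
      "pool G6P 6",
      "pool TP 3",
      "pool PEP 3",
      "pool PYR 3",
      "pool MAL 4",
      "pool ACA 2",
      "pool CO2 1",
      "pool ACA.out 2 sink",
      "pool MAL.out 4 sink",
      "pool CO2.eff 1 sink",
      "substrate GLC.ext enrichment=0.6",
      "fixed upt = 1",
      "free dil ana out_mal",
      "measure G6P : G6P",
      "measure TP : TP",
      "measure PEP : PEP",
      "measure PYR : PYR",
      "measure MAL : MAL unlabelled=free",
      "upt: GLC.ext (abcdef) -> G6P (abcdef)",
      "dil: GLC.v (abcdef) -> G6P (abcdef) | class=transport",
      "gly1: G6P (abcdef) -> TP (cba) + TP (def) | class=hexose",
      "gly2: TP (abc) <-> PEP (abc) | class=hexose",
      "pk: PEP (abc) -> PYR (abc) | class=hexose",
      "ana: PEP (abc) + CO2 (d) -> MAL (abcd) | class=anaplerotic",
      "me: MAL (abcd) -> PYR (abc) + CO2 (d) | class=anaplerotic",
      "pdh: PYR (abc) -> ACA (bc) + CO2 (a) | class=TCA",
      "out_aca: ACA (ab) -> ACA.out (ab) | class=output",
      "out_mal: MAL (abcd) -> MAL.out (abcd) | class=output",
      "co2out: CO2 (a) -> CO2.eff (a) | class=output"),
    chain2 = c(
      "pool S 2 source",
      "pool A 2",
      "pool B 2",
      "pool OUT 2 sink",
      "substrate S enrichment=0.6",
      "fixed in = 1",
      "measure A : A",
      "measure B : B",
      "in: S (ab) -> A (ab)",
      "mid: A (ab) -> B (ab)",
      "out: B (ab) -> OUT (ab)"),
    condense = c(
      "pool SA 1 source",
      "pool SB 1 source",
      "pool C 2",
      "pool OUT 2 sink",
      "substrate SA enrichment=0.5",
      "substrate SB enrichment=0.5",
      "fixed syn = 1",
      "measure C : C",
      "syn: SA (a) + SB (b) -> C (ab)",
      "out: C (ab) -> OUT (ab)"),
    branch = c(
      "pool S1 2 source",
      "pool S2 2 source",
      "pool A 2",
      "pool OUT 2 sink",
      "substrate S1 enrichment=1",
      "fixed in1 = 0.5",
      "fixed in2 = 0.5",
      "measure A : A",
      "in1: S1 (ab) -> A (ab)",
      "in2: S2 (ab) -> A (ab)",
      "out: A (ab) -> OUT (ab)"),
    symmetric = c(
      "pool S 2 source",
      "pool SY 2 symmetric",
      "pool D 2",
      "pool OUT 2 sink",
      "substrate S pattern=10:0.5,00:0.5",
      "fixed in = 1",
      "measure D : D",
      "in: S (ab) -> SY (ab)",
      "mid: SY (ab) -> D (ab)",
      "out: D (ab) -> OUT (ab)"),
    arabidopsis = c(
      "# transcribed compartmented central carbon metabolism network",
      "# (.c cytosol, .p plastid, .m mitochondrion, .v vacuole)",
      "pool GLC.med 6 source",
      "pool GLC.v 6 source",
      "pool GLC.int 6",
      "pool G6P.c 6",
      "pool F6P.c 6",
      "pool FBP.c 6",
      "pool TP.c 3",
      "pool 3PG.c 3",
      "pool PEP.c 3",
      "pool PYR.c 3",
      "pool G6P.p 6",
      "pool F6P.p 6",
      "pool FBP.p 6",
      "pool TP.p 3",
      "pool 3PG.p 3",
      "pool PEP.p 3",
      "pool PYR.p 3",
      "pool PYR.m 3",
      "pool 6PG.c 6",
      "pool 6PG.p 6",
      "pool RU5P.p 5",
      "pool R5P.p 5",
      "pool X5P.p 5",
      "pool S7P.p 7",
      "pool E4P.p 4",
      "pool TKC2.p 2",
      "pool TAC3.p 3",
      "pool AcCoA 2",
      "pool MAL 4",
      "pool CIT 6",
      "pool ICIT 6",
      "pool 2OG 5",
      "pool SUCCCoA 4",
      "pool SUCC 4 symmetric",
      "pool FUM 4 symmetric",
      "pool CO2 1",
      "pool G1P.p 6",
      "pool G1P.c 6",
      "pool UDPG 6",
      "pool CO2.eff 1 sink",
      "pool STARCH 6 sink",
      "pool S6P 12 sink",
      "pool PYRP.out 3 sink",
      "pool PYRC.out 3 sink",
      "pool ACA.out 2 sink",
      "pool E4P.out 4 sink",
      "pool UDPG.out 6 sink",
      "pool X2OG.out 5 sink",
      "pool CIT.out 6 sink",
      "pool SUCC.out 4 sink",
      "pool MAL.out 4 sink",
      "pool R5P.out 5 sink",
      "substrate GLC.med enrichment=0.6",
      "fixed upt = 1",
      "free Glcv chex3 ana1 ana2 ana3 cpex cmex cppp1 pppp1 pppp2a pppp2c out2og outcit outsuc phex45 chex45 chex6 chex1 tca2",
      "measure G6P : G6P.c,G6P.p weights=free",
      "measure PEP : PEP.c,PEP.p weights=free",
      "measure PYR : PYR.c,PYR.p,PYR.m weights=free",
      "measure MAL : MAL unlabelled=free",
      "measure CIT : CIT unlabelled=free",
      "measure 2OG : 2OG",
      "measure SUCC : SUCC unlabelled=free",
      "med: GLC.med (abcdef) -> GLC.int (abcdef) | class=transport",
      "Glcv: GLC.v (abcdef) -> GLC.int (abcdef) | class=transport",
      "upt: GLC.int (abcdef) -> G6P.c (abcdef) | class=hexose",
      "chex1: G6P.c (abcdef) <-> F6P.c (abcdef) | class=hexose",
      "pfkc: F6P.c (abcdef) -> FBP.c (abcdef) | class=hexose",
      "chex2: FBP.c (abcdef) <-> TP.c (cba) + TP.c (def) | class=hexose",
      "chex3-1: TP.c (abc) <-> 3PG.c (abc) | class=hexose",
      "chex3-2: 3PG.c (abc) <-> PEP.c (abc) | class=hexose",
      "chex3: PEP.c (abc) -> PYR.c (abc) | class=hexose",
      "phex1: G6P.p (abcdef) <-> F6P.p (abcdef) | class=hexose",
      "pfkp: F6P.p (abcdef) -> FBP.p (abcdef) | class=hexose",
      "phex2: FBP.p (abcdef) <-> TP.p (cba) + TP.p (def) | class=hexose",
      "phex3-1: TP.p (abc) <-> 3PG.p (abc) | class=hexose",
      "phex3-2: 3PG.p (abc) <-> PEP.p (abc) | class=hexose",
      "phex3: PEP.p (abc) -> PYR.p (abc) | class=hexose",
      "cppp1: G6P.c (abcdef) -> 6PG.c (abcdef) | class=PPP",
      "cppp2: 6PG.c (abcdef) -> CO2 (a) + R5P.p (bcdef) | class=PPP",
      "pppp1: G6P.p (abcdef) -> 6PG.p (abcdef) | class=PPP",
      "pppp1b: 6PG.p (abcdef) -> CO2 (a) + RU5P.p (bcdef) | class=PPP",
      "ppi: RU5P.p (abcde) <-> R5P.p (abcde) | class=PPP",
      "ppe: RU5P.p (abcde) <-> X5P.p (abcde) | class=PPP",
      "pppp2a: R5P.p (abcde) + TKC2.p (fg) <-> S7P.p (fgabcde) | class=PPP",
      "pppp2b: E4P.p (abcd) + TKC2.p (ef) <-> F6P.p (efabcd) | class=PPP",
      "pppp2c: X5P.p (abcde) <-> TP.p (cde) + TKC2.p (ab) | class=PPP",
      "pppp3a: S7P.p (abcdefg) <-> E4P.p (defg) + TAC3.p (abc) | class=PPP",
      "pppp3b: TP.p (abc) + TAC3.p (def) <-> F6P.p (defabc) | class=PPP",
      "cmex: PYR.c (abc) -> PYR.m (abc) | class=transport",
      "cpex: PYR.c (abc) -> PYR.p (abc) | class=transport",
      "gpt: G6P.c (abcdef) <-> G6P.p (abcdef) | class=transport",
      "tpt: TP.c (abc) <-> TP.p (abc) | class=transport",
      "tca1: PYR.m (abc) -> CO2 (a) + AcCoA (bc) | class=TCA",
      "tca2: AcCoA (ef) + MAL (abcd) -> CIT (dcbfea) | class=TCA",
      "aco: CIT (abcdef) <-> ICIT (abcdef) | class=TCA",
      "tca3: ICIT (abcdef) -> CO2 (f) + 2OG (abcde) | class=TCA",
      "tca4: 2OG (abcde) -> CO2 (a) + SUCCCoA (bcde) | class=TCA",
      "scs: SUCCCoA (abcd) -> SUCC (abcd) | class=TCA",
      "tca5: SUCC (abcd) <-> FUM (abcd) | class=TCA",
      "tca6: FUM (abcd) <-> MAL (abcd) | class=TCA",
      "ana1: PEP.c (abc) + CO2 (d) <-> MAL (abcd) | class=anaplerotic",
      "ana2: MAL (abcd) -> PYR.m (abc) + CO2 (d) | class=anaplerotic",
      "ana3: MAL (abcd) -> PYR.p (abc) + CO2 (d) | class=anaplerotic",
      "CO2out: CO2 (a) -> CO2.eff (a) | class=output",
      "phex45: G6P.p (abcdef) <-> G1P.p (abcdef) | class=synthesis",
      "starch: G1P.p (abcdef) -> STARCH (abcdef) | class=output",
      "chex45: G6P.c (abcdef) <-> G1P.c (abcdef) | class=synthesis",
      "ugp: G1P.c (abcdef) -> UDPG (abcdef) | class=synthesis",
      "chex6: F6P.c (abcdef) + UDPG (ghijkl) -> S6P (abcdefghijkl) | class=output",
      "outpyrp: PYR.p (abc) -> PYRP.out (abc) | class=output",
      "outpyrc: PYR.c (abc) -> PYRC.out (abc) | class=output",
      "outaca: AcCoA (ab) -> ACA.out (ab) | class=output",
      "oute4p: E4P.p (abcd) -> E4P.out (abcd) | class=output",
      "outudpg: UDPG (abcdef) -> UDPG.out (abcdef) | class=output",
      "out2og: 2OG (abcde) -> X2OG.out (abcde) | class=output",
      "outcit: CIT (abcdef) -> CIT.out (abcdef) | class=output",
      "outsuc: SUCC (abcd) -> SUCC.out (abcd) | class=output",
      "outmal: MAL (abcd) -> MAL.out (abcd) | class=output",
      "outr5p: R5P.p (abcde) -> R5P.out (abcde) | class=output")
  )
}

#' Ground-truth flux states for the desk network
#'
#' Returns the balanced flux state used as the default synthetic-experiment
#' truth. The `"control"` condition transcribes published control-condition
#' values where the compact network has a counterpart (glucose uptake 1.000,
#' unlabelled glucose influx 0.162, anaplerotic carboxylation 0.838); the
#' `"stress"` condition lowers the pyruvate-kinase branch and raises
#' anaplerosis (unlabelled influx 0.113, carboxylation 1.243), mirroring the
#' published oxidative-stress flux shifts. Pool sizes spread turnover times
#' from below a minute (triose phosphates) to tens of minutes (malate).
#'
#' @param condition `"control"` or `"stress"`.
#' @return a [flux_state()] for [mfa_example_model()]'s `"desk"` network.
#' @export
desk_truth <- function(condition = c("control", "stress")) {
  condition <- match.arg(condition)
  model <- mfa_example_model("desk")
  free <- switch(condition,
    control = c(dil = 0.162, ana = 0.838, out_mal = 0.2),
    stress  = c(dil = 0.113, ana = 1.243, out_mal = 0.2))
  flux_state(model, free = free, exchange = c(gly2 = 0.3),
             pools = c(G6P = 5, TP = 0.8, PEP = 1.2, PYR = 3, MAL = 20, CO2 = 1.5))
}

#' Reference flux state of the transcribed arabidopsis network
#'
#' Balances the bundled `"arabidopsis"` network at the published
#' control-condition flux values where a free flux has a direct published
#' counterpart (glucose uptake 1.000, unlabelled glucose input 0.162,
#' pyruvate kinase 0.477, anaplerotic fluxes 0.838/0.625, TCA citrate
#' synthase 0.972, starch/sucrose synthesis 0.061/0.098/0.059, PPP fluxes
#' 0.004/-0.004). Dependent fluxes then reproduce the remaining published
#' values up to their printed rounding (e.g. cytosolic aldolase 0.540,
#' plastidic aldolase 0.234, TCA steps 0.998-0.801); output fluxes added to
#' close pool balances (pyruvate, acetyl-CoA, erythrose-4-phosphate,
#' UDP-glucose withdrawals to biomass) absorb small published-table
#' inconsistencies, so the total CO2 efflux comes out slightly below the
#' printed value. Pool sizes default to 1 (relative units) for every
#' balanced pool.
#'
#' @return a [flux_state()] for the `"arabidopsis"` model.
#' @export
arabidopsis_reference_state <- function() {
  model <- mfa_example_model("arabidopsis")
  free <- c(Glcv = 0.162, chex3 = 0.477, ana1 = 0.838, ana2 = 0.625, ana3 = 0,
            cpex = 0, cmex = 0.373, cppp1 = 0, pppp1 = 0.004, pppp2a = 0.004,
            pppp2c = -0.004, out2og = 0.132, outcit = 0.029, outsuc = 0.010,
            phex45 = 0.061, chex45 = 0.098, chex6 = 0.059, chex1 = 0.599,
            tca2 = 0.972)
  bal <- model$pools$name[model$pools$role == "balanced"]
  flux_state(model, free = free,
             pools = stats::setNames(rep(1, length(bal)), bal))
}

#' Default mixing values of the desk network's free measurement parameters
#' @param condition passed through for symmetry; both conditions share the
#'   same extraction mixing.
#' @return named list usable as `mixing` in [simulate_mids()].
#' @export
desk_mixing <- function(condition = "control") {
  list(MAL = list(unlabelled = 0.3))
}
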