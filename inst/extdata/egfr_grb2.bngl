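# Simplified EGFR/Grb2 signaling model used throughout the documentation.
# EGFR carries an extracellular ligand-binding domain (l), a transmembrane
# dimerization domain (r) and two cytoplasmic tyrosines (Y1068, Y1148) that
# toggle between unphosphorylated (u) and phosphorylated (p).
begin parameters
  kp1 0.1
  km1 0.05
  kp2 1.0
  km2 0.1
  kphos 2.0
  kdephos 0.5
  kproc 0.2
  kdeg 0.01
end parameters
begin molecule types
  EGF(r)
  proEGF(pro,egf)
  EGFR(l,r,Y1068~u~p,Y1148~u~p)
  Grb2(SH2,SH3)
  PTP()
  Src(SH2)
end molecule types
begin seed species
  EGFR(l,r,Y1068~u,Y1148~u) 100
  Grb2(SH2,SH3) 50
  PTP() 10
end seed species
begin observables
  Molecules EGFR_Y1068p EGFR(Y1068~p)   # phosphorylated receptors, any context
  Molecules EGFR_dimer_opt EGFR(r!+,Y1148!?)
end observables
begin reaction rules
  grb2_bind: EGFR(Y1068~p) + Grb2(SH2,SH3) -> EGFR(Y1068~p!1).Grb2(SH2!1,SH3) kp1
  grb2_bind_rev: EGFR(Y1068~p) + Grb2(SH2,SH3) <-> EGFR(Y1068~p!1).Grb2(SH2!1,SH3) kp1, km1
  grb2_intra: Grb2(SH2,SH3!+).EGFR(Y1068~p) <-> Grb2(SH2!1,SH3!+).EGFR(Y1068~p!1) kp2, km2
  transphos: EGFR(r!1,Y1068~u).EGFR(r!1) -> EGFR(r!1,Y1068~p).EGFR(r!1) kphos
  dephos: EGFR(Y1068~p) + PTP() -> EGFR(Y1068~u) + PTP() kdephos
  proegf_processing: proEGF(pro,egf) -> EGF(r) kproc
  egf_degradation: EGF(r!1).EGFR(l!1) -> EGFR(l) kdeg
end reaction rules
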