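# Default adult vaping exposure scenario (EPA default adult + vaping topography)
bw: 70                 # body weight, kg
t_puffs: 163           # puffs per day
breathing_volume: 20   # m3 of air inhaled per day (reference-dose conversion)
ci: 0.05               # chronic e-liquid contact volume, ml/day (leakage)
ai: 10                 # acute intake volume, ml (one accidental ingestion)
ef: 365                # exposure frequency, days/year
ed: 70                 # exposure duration, years
at: 25550              # averaging time, days (= ed * 365)
sa: 5700               # exposed skin area, cm2
af: 0.2                # skin adherence factor, mg/(cm2 day)
cf: 1                  # unit conversion factor (canonical units are consistent)
abs_paper: 0.03        # dermal absorption fraction applied to every chemical
                       # in paper_replication mode
abs_as_stated:         # dermal absorption fractions in as_stated mode
  As: 0.03
  default: 0.001
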