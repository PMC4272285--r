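# Quadrat search experiment: 14 observers each search 9 quadrats for 15
# minutes, recording time to first detection. Rate units: detections per
# minute; times in minutes. The default rate is the tussock-forming species
# (mu = 0.56, sigma = 0.64); the prostrate species had mu = 0.55,
# sigma = 0.60.
rate:
  mu: 0.56
  sigma: 0.64
design:
  B: [5, 10, 15]
  c: [0.25, 0.5, 1]
Q_c: 0.05
layout:
  observers: 14
  quadrats: 9
session_length: 15
search_time: 15
abundance: 1
beta: 1
seed: 1
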