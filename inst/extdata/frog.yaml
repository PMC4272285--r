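# Stream-transect scenario: nocturnal frog surveys over a 90-night season.
# Rate units: detections per person-hour; times in hours.
rate:
  mu: 0.67        # mean rate at abundance 1; rises to 2.2 at abundance 3
  theta: 2.5
correlation:
  r: 0.3          # night-to-night correlation of log rates
  structure: ar1
  T: 90
design:
  B: 10
  c: 1
Q_c: 0.05
layout:
  sites: 29
  visits: [2, 3, 3, 4, 2, 3, 5, 3, 2, 9, 3, 4, 2, 3, 3, 2, 4, 3, 3, 2, 5, 3, 4, 2, 3, 3, 6, 2, 3]
search_time: 1
session_length: 1
abundance: [1, 3]
beta: 1.0824      # log-linear abundance effect: mu(3) = 2.2 = 0.67 * 3^beta
seed: 1
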