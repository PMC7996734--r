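# Simplified Turner-style nearest-neighbour parameters, 37 C, kcal/mol.
# stack P1 P2 dG : pair (i,j)=P1 stacked on (i+1,j-1)=P2
# hairpin/bulge/internal n dG : loop initiation by unpaired length n
# multiloop closing|branch|unpaired dG : affine multiloop model
stack AU AU -0.93
stack AU CG -2.24
stack AU GC -2.08
stack AU GU -0.55
stack AU UA -1.10
stack AU UG -1.36
stack CG AU -2.11
stack CG CG -3.26
stack CG GC -2.36
stack CG GU -1.41
stack CG UA -2.08
stack CG UG -2.11
stack GC AU -2.35
stack GC CG -3.42
stack GC GC -3.26
stack GC GU -1.53
stack GC UA -2.24
stack GC UG -2.51
stack GU AU -1.27
stack GU CG -2.51
stack GU GC -2.11
stack GU GU -0.50
stack GU UA -1.36
stack GU UG 1.29
stack UA AU -1.33
stack UA CG -2.35
stack UA GC -2.11
stack UA GU -1.00
stack UA UA -0.93
stack UA UG -1.27
stack UG AU -1.00
stack UG CG -1.53
stack UG GC -1.41
stack UG GU 0.30
stack UG UA -0.55
stack UG UG -0.50
hairpin 3 5.4
hairpin 4 5.6
hairpin 5 5.7
hairpin 6 5.4
hairpin 7 6.0
hairpin 8 5.5
hairpin 9 6.4
bulge 1 3.8
bulge 2 2.8
bulge 3 3.2
bulge 4 3.6
bulge 5 4.0
bulge 6 4.4
internal 2 0.5
internal 3 1.6
internal 4 1.7
internal 5 1.8
internal 6 2.0
multiloop closing 3.4
multiloop branch 0.4
multiloop unpaired 0.0
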