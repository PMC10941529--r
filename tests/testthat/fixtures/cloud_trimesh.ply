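ply
format ascii 1.0
comment https://github.com/mikedh/trimesh
element vertex 24
property float x
property float y
property float z
end_header
-6.53934622 -19.48630142 9.89175510
8.49979877 -8.82437992 -1.99351001
-36.07384491 -17.64759636 4.33176184
11.91094971 -0.17949501 -16.45500565
-7.10219622 10.50632572 -27.33413887
24.09546661 -4.57197905 -16.10060883
-20.78919792 -22.58330727 15.25949383
-27.09574127 -16.85023689 2.03882408
-24.25850487 -23.10755157 33.75654602
-2.89703608 -7.47297382 42.97578049
19.93011665 11.52863216 17.35515022
11.35435200 2.62128496 -46.75517654
13.00155258 -2.78164101 30.43769455
19.95490837 27.15862083 -8.04821014
9.11342525 26.27963638 -19.94149017
-2.69974995 -10.82491875 3.97769403
-1.62680805 -6.97724819 16.64958000
10.33355141 16.53093910 13.17551994
-26.30856895 3.50380707 -14.03889656
31.27147675 -1.55311298 22.34624481
13.34337139 2.47464204 -26.92358971
-5.60355711 7.90939188 19.09402657
34.85679245 9.44608784 41.80614090
-7.32300520 6.07186699 -7.01737118
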