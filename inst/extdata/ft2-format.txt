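FT2 dialect read and written by this package
============================================

FT2 is a plain-text centroided spectrum format produced by the Raxport raw
file converter. There is no formal standard; this note pins the dialect the
package reads and writes.

Header lines (optional, file level):
  H <key> <value>

Per scan:
  S <scan> <scan> [<precursor m/z>]   scan number (low/high are equal for
                                      centroided data); the fourth field is
                                      present for data-dependent MS2 scans
  Z <charge> <mass>                   precursor charge and neutral mass
  I <key> <value>                     metadata; RetentionTime (minutes) and
                                      MSLevel are interpreted, any other key
                                      is preserved verbatim
  <m/z> <intensity> [resolution baseline noise charge]
                                      one line per centroided peak; only the
                                      first two columns are required

Fields are separated by tabs or spaces. Example with two scans:

S	1	1
I	RetentionTime	10.000000
I	MSLevel	1
400.000000	100000.000000
500.000000	250000.000000
S	2	2	500.000000
Z	2	997.985447
I	RetentionTime	10.010000
I	MSLevel	2
200.100000	5000.000000
300.200000	8000.000000
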