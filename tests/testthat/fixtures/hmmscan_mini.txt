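# hmmscan :: search sequence(s) against a profile database
# HMMER 3.4 (Aug 2023); http://hmmer.org/
Query:       q1  [L=40]
Scores for complete sequence (score includes all domains):
   --- full sequence ---   --- best 1 domain ---    -#dom-
    E-value  score  bias    E-value  score  bias    exp  N  Model    Description
    ------- ------ -----    ------- ------ -----   ---- --  -------- -----------
    1.0e-15   50.0   0.0    1.0e-15   50.0   0.0    1.0  1  DOMA     test domain A
    5.0e-09   28.0   0.0    5.0e-09   28.0   0.0    1.0  1  DOMB     test domain B

Domain annotation for each model (and alignments):
>> DOMA  test domain A
   #    score  bias  c-Evalue  i-Evalue  hmmfrom  hmm to    alifrom  ali to    envfrom  env to     acc
 ---   ------ ----- --------- --------- ------- -------    ------- -------    ------- -------    ----
   1 !   50.0   0.0   2.0e-20   1.0e-15       3      10 ..       5      12 ..       4      13 .. 0.98

  Alignments for each domain:
  == domain 1  score: 50.0 bits;  conditional E-value: 2.0e-20
         DOMA   3 ABCD.EFGH 10
                  ABCD EF H
           q1   5 ABCDxEF-H 12
                  899999*.9 PP

>> DOMB  test domain B
   #    score  bias  c-Evalue  i-Evalue  hmmfrom  hmm to    alifrom  ali to    envfrom  env to     acc
 ---   ------ ----- --------- --------- ------- -------    ------- -------    ------- -------    ----
   1 !   28.0   0.0   9.0e-12   5.0e-09       1       4 ..      20      23 ..      20      23 .. 0.95

  Alignments for each domain:
  == domain 1  score: 28.0 bits;  conditional E-value: 9.0e-12
         DOMB   1 WXYZ 4
                  WXYZ
           q1  20 WXYZ 23
                  9*** PP



Internal pipeline statistics summary:
-------------------------------------
Query sequence(s):                         1  (40 residues searched)
//
[ok]
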