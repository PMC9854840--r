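n_landmarks: 40
pairs:
- - 2
  - 3
- - 4
  - 5
- - 6
  - 7
- - 8
  - 9
- - 10
  - 11
- - 12
  - 13
- - 14
  - 15
- - 16
  - 17
- - 18
  - 19
- - 20
  - 21
- - 22
  - 23
- - 24
  - 25
- - 26
  - 27
- - 28
  - 29
- - 30
  - 31
- - 32
  - 33
- - 36
  - 37
- - 38
  - 39
midline:
- 1
- 34
- 35
- 40
semilandmarks:
- - 18
  - 8
  - 20
- - 20
  - 18
  - 10
- - 19
  - 9
  - 21
- - 21
  - 19
  - 11
- - 22
  - 10
  - 24
- - 24
  - 22
  - 26
- - 26
  - 24
  - 28
- - 28
  - 26
  - 16
- - 23
  - 11
  - 25
- - 25
  - 23
  - 27
- - 27
  - 25
  - 29
- - 29
  - 27
  - 17
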