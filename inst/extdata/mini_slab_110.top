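# nanosorb topology: 64 atoms
[ bonds ]
1 4
1 16
1 17
2 3
2 15
2 18
3 6
3 19
4 5
4 20
5 8
5 27
6 7
6 28
7 10
7 21
8 9
8 22
9 12
9 29
10 11
10 30
11 14
11 31
12 13
12 32
13 16
13 23
14 15
14 24
15 25
16 26
17 19
17 25
17 33
18 20
18 26
18 34
19 27
19 37
20 28
20 38
21 27
21 29
21 41
22 28
22 30
22 42
23 25
23 31
23 47
24 26
24 32
24 48
25 35
26 36
27 39
28 40
29 31
29 43
30 32
30 44
31 45
32 46
33 36
33 38
33 49
34 35
34 37
34 50
35 48
35 63
36 47
36 64
37 40
37 51
38 39
38 52
39 42
39 53
40 41
40 54
41 44
41 55
42 43
42 56
43 46
43 57
44 45
44 58
45 48
45 59
46 47
46 60
47 61
48 62
49 51
49 63
50 52
50 64
51 53
52 54
53 55
54 56
55 57
56 58
57 59
58 60
59 61
60 62
61 63
62 64
[ angles ]
4 1 16
4 1 17
16 1 17
3 2 15
3 2 18
15 2 18
2 3 6
2 3 19
6 3 19
1 4 5
1 4 20
5 4 20
4 5 8
4 5 27
8 5 27
3 6 7
3 6 28
7 6 28
6 7 10
6 7 21
10 7 21
5 8 9
5 8 22
9 8 22
8 9 12
8 9 29
12 9 29
7 10 11
7 10 30
11 10 30
10 11 14
10 11 31
14 11 31
9 12 13
9 12 32
13 12 32
12 13 16
12 13 23
16 13 23
11 14 15
11 14 24
15 14 24
2 15 14
2 15 25
14 15 25
1 16 13
1 16 26
13 16 26
1 17 19
1 17 25
1 17 33
19 17 25
19 17 33
25 17 33
2 18 20
2 18 26
2 18 34
20 18 26
20 18 34
26 18 34
3 19 17
3 19 27
3 19 37
17 19 27
17 19 37
27 19 37
4 20 18
4 20 28
4 20 38
18 20 28
18 20 38
28 20 38
7 21 27
7 21 29
7 21 41
27 21 29
27 21 41
29 21 41
8 22 28
8 22 30
8 22 42
28 22 30
28 22 42
30 22 42
13 23 25
13 23 31
13 23 47
25 23 31
25 23 47
31 23 47
14 24 26
14 24 32
14 24 48
26 24 32
26 24 48
32 24 48
15 25 17
15 25 23
15 25 35
17 25 23
17 25 35
23 25 35
16 26 18
16 26 24
16 26 36
18 26 24
18 26 36
24 26 36
5 27 19
5 27 21
5 27 39
19 27 21
19 27 39
21 27 39
6 28 20
6 28 22
6 28 40
20 28 22
20 28 40
22 28 40
9 29 21
9 29 31
9 29 43
21 29 31
21 29 43
31 29 43
10 30 22
10 30 32
10 30 44
22 30 32
22 30 44
32 30 44
11 31 23
11 31 29
11 31 45
23 31 29
23 31 45
29 31 45
12 32 24
12 32 30
12 32 46
24 32 30
24 32 46
30 32 46
17 33 36
17 33 38
17 33 49
36 33 38
36 33 49
38 33 49
18 34 35
18 34 37
18 34 50
35 34 37
35 34 50
37 34 50
25 35 34
25 35 48
25 35 63
34 35 48
34 35 63
48 35 63
26 36 33
26 36 47
26 36 64
33 36 47
33 36 64
47 36 64
19 37 34
19 37 40
19 37 51
34 37 40
34 37 51
40 37 51
20 38 33
20 38 39
20 38 52
33 38 39
33 38 52
39 38 52
27 39 38
27 39 42
27 39 53
38 39 42
38 39 53
42 39 53
28 40 37
28 40 41
28 40 54
37 40 41
37 40 54
41 40 54
21 41 40
21 41 44
21 41 55
40 41 44
40 41 55
44 41 55
22 42 39
22 42 43
22 42 56
39 42 43
39 42 56
43 42 56
29 43 42
29 43 46
29 43 57
42 43 46
42 43 57
46 43 57
30 44 41
30 44 45
30 44 58
41 44 45
41 44 58
45 44 58
31 45 44
31 45 48
31 45 59
44 45 48
44 45 59
48 45 59
32 46 43
32 46 47
32 46 60
43 46 47
43 46 60
47 46 60
23 47 36
23 47 46
23 47 61
36 47 46
36 47 61
46 47 61
24 48 35
24 48 45
24 48 62
35 48 45
35 48 62
45 48 62
33 49 51
33 49 63
51 49 63
34 50 52
34 50 64
52 50 64
37 51 49
37 51 53
49 51 53
38 52 50
38 52 54
50 52 54
39 53 51
39 53 55
51 53 55
40 54 52
40 54 56
52 54 56
41 55 53
41 55 57
53 55 57
42 56 54
42 56 58
54 56 58
43 57 55
43 57 59
55 57 59
44 58 56
44 58 60
56 58 60
45 59 57
45 59 61
57 59 61
46 60 58
46 60 62
58 60 62
47 61 59
47 61 63
59 61 63
48 62 60
48 62 64
60 62 64
35 63 49
35 63 61
49 63 61
36 64 50
36 64 62
50 64 62
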